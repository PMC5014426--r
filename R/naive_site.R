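# Naive-site reconstruction and empty-site search. Excising an element
# together with one copy of its target-site duplication reconstructs the
# pre-insertion ("naive") sequence; finding that junction intact in the
# other strain demonstrates an empty allelic site and rules out the
# degenerated-relic explanation for an apparently missing element.

#' Reconstruct the naive (pre-insertion) site of a TE
#'
#' The element, one TSD copy and any TSD offset bases are excised; `window`
#' bp of flank is kept on each side of the single remaining TSD copy, so
#' the result has length `2 * window + tsd_length` away from chromosome
#' ends.
#'
#' @param genome `GenomeAssembly` of the strain carrying the element.
#' @param te List or one-row data.frame with `seqid`, `start`, `end`
#'   (element interval, 0-based half-open, LTR start to LTR end) and
#'   optionally `tsd_len`, `tsd_offset` (0 when absent, flagged).
#' @param window Flank retained on each side, bp.
#' @return A `NaiveSite` list: `seq`, `junction` (0-based offset of the
#'   downstream flank within `seq`), `tsd_len`, `offset`, `window`, and
#'   flags `no_tsd`, `truncated`.
#' @export
reconstruct_naive_site <- function(genome, te, window = 500L) {
  L <- te$tsd_len
  o <- te$tsd_offset
  no_tsd <- is.null(L) || is.na(L)
  if (no_tsd) { L <- 0L; o <- 0L }
  if (is.null(o) || is.na(o)) o <- 0L
  chrom_len <- chrom_lengths(genome)[[te$seqid]]
  up_hi <- te$start - o                  # upstream flank (incl. TSD copy) ends here
  up_lo <- max(0L, up_hi - window - L)
  down_lo <- te$end + L                  # downstream TSD copy excised
  down_hi <- min(chrom_len, down_lo + window)
  truncated <- (up_hi - up_lo) < window + L || (down_hi - down_lo) < window
  seq <- paste0(genome_subseq(genome, te$seqid, up_lo, up_hi),
                genome_subseq(genome, te$seqid, down_lo, down_hi))
  list(seq = seq, junction = up_hi - up_lo, tsd_len = L, offset = o,
       window = window, no_tsd = no_tsd, truncated = truncated)
}

# exact-probe localization of a sequence half in a genome; returns implied
# 0-based start positions of the whole naive sequence, per chromosome
probe_implied_starts <- function(seq, lo, hi, genome, k, n_probes) {
  if (hi - lo < k) return(NULL)
  starts <- unique(as.integer(round(seq(lo, hi - k, length.out = n_probes))))
  out <- list()
  for (chrom in names(genome$chromosomes)) {
    subj <- Biostrings::DNAString(genome$chromosomes[[chrom]])
    implied <- integer()
    for (st in starts) {
      pb <- s_sub(seq, st, st + k)
      if (grepl("N", pb, fixed = TRUE)) next
      hits <- Biostrings::start(Biostrings::matchPattern(pb, subj)) - 1L
      if (length(hits) >= 1L && length(hits) <= 5L) {
        implied <- c(implied, hits - st)
      }
    }
    if (length(implied)) out[[chrom]] <- implied
  }
  out
}

#' Search another genome for the empty (naive) site
#'
#' Localizes the two halves of the naive junction sequence in the other
#' genome by exact probe k-mers. The site is reported found only when the
#' two halves land contiguously (no element-sized gap at the junction) and
#' the full naive sequence aligns at `min_identity` identity over at least
#' `min_coverage` of its length.
#'
#' @param naive Result of [reconstruct_naive_site].
#' @param other_genome `GenomeAssembly` to search.
#' @param min_identity Identity threshold for the aligned site.
#' @param min_coverage Fraction of the naive sequence that must align.
#' @param max_junction_gap Largest insertion (bp) at the junction still
#'   counted as contiguous.
#' @param probe_k,n_probes Probe tuning.
#' @return List with `found`, and when found `chrom`, `position`,
#'   `identity`, `coverage`.
#' @export
locate_empty_site <- function(naive, other_genome, min_identity = 0.90,
                              min_coverage = 0.90, max_junction_gap = 50L,
                              probe_k = 21L, n_probes = 5L) {
  nseq <- naive$seq
  n <- nchar(nseq)
  stopifnot(n >= 60L)
  j <- naive$junction
  up <- probe_implied_starts(nseq, 0L, j, other_genome, probe_k, n_probes)
  down <- probe_implied_starts(nseq, j + naive$tsd_len, n, other_genome,
                               probe_k, n_probes)
  notfound <- list(found = FALSE)
  chroms <- intersect(names(up), names(down))
  if (!length(chroms)) return(notfound)
  for (chrom in chroms) {
    mu <- stats::median(up[[chrom]])
    md <- stats::median(down[[chrom]])
    if (abs(md - mu) > max_junction_gap) next  # junction interrupted
    start <- as.integer(round((mu + md) / 2))
    clen <- chrom_lengths(other_genome)[[chrom]]
    lo <- max(0L, start - 100L)
    hi <- min(clen, start + n + 100L)
    region <- genome_subseq(other_genome, chrom, lo, hi)
    pa <- Biostrings::pairwiseAlignment(
      nseq, region, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE),
      gapOpening = 6, gapExtension = 1
    )
    nm <- Biostrings::nmatch(pa)
    nx <- Biostrings::nmismatch(pa)
    idy <- if (nm + nx > 0) nm / (nm + nx) else 0
    cov <- IRanges::width(pa@pattern@range) / n
    # no element-sized indel inside the aligned junction
    indel_w <- c(IRanges::width(Biostrings::indel(pa)@insertion[[1L]]),
                 IRanges::width(Biostrings::indel(pa)@deletion[[1L]]))
    if (idy >= min_identity && cov >= min_coverage &&
        (!length(indel_w) || max(indel_w) <= max_junction_gap)) {
      return(list(found = TRUE, chrom = chrom,
                  position = lo + IRanges::start(pa@subject@range) - 1L,
                  identity = idy, coverage = cov))
    }
  }
  notfound
}
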