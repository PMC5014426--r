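# Per-family element census by homology search against family reference
# sequences. The homology search itself is delegated to blastn; hit
# merging and length-class assignment (full-length / partial / fragment)
# are done here.

run_blastn <- function(genome_fa, query_fa, perc_identity = 80) {
  blastn <- Sys.which("blastn")
  makedb <- Sys.which("makeblastdb")
  if (blastn == "" || makedb == "") {
    stop("blastn/makeblastdb not found on PATH; census_elements requires BLAST+")
  }
  db <- tempfile("blastdb")
  out <- tempfile("blast", fileext = ".tsv")
  st <- system2(makedb, c("-in", genome_fa, "-dbtype", "nucl", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed")
  st <- system2(blastn, c("-task", "blastn", "-query", query_fa, "-db", db,
                          "-outfmt", "6", "-dust", "no", "-evalue", "1e-5",
                          "-perc_identity", as.character(perc_identity),
                          "-out", out),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastn failed")
  if (file.size(out) == 0L) {
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      sstart = integer(), send = integer()))
  }
  df <- utils::read.table(out, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
  df
}

#' Census of transposable-element families in a genome
#'
#' Finds homology hits of each family reference in the genome, merges
#' overlapping hits of one family, and classifies merged hits by length:
#' full-length (at least `full_length_fraction` of the reference length),
#' partial (> `partial_min` bp), fragment (`fragment_min` bp to
#' `partial_min` bp); shorter hits are discarded. One length rule serves
#' families of very different reference size because the full-length
#' threshold is a fraction, not a fixed bp value.
#'
#' @param genome A `GenomeAssembly`.
#' @param family_refs Named character vector: one reference sequence per
#'   family.
#' @param full_length_fraction Fraction of the reference length above which
#'   a merged hit is full-length.
#' @param partial_min,fragment_min Length-class boundaries in bp.
#' @param min_identity Minimum percent identity (0-1) for hits.
#' @return List with `census` (data.frame: `family`, `full`, `partial`,
#'   `fragment`) and `hits` (data.frame of merged hits with `family`,
#'   `seqid`, `start`, `end` 0-based half-open, `class`).
#' @export
census_elements <- function(genome, family_refs, full_length_fraction = 0.92,
                            partial_min = 1000L, fragment_min = 30L,
                            min_identity = 0.80) {
  stopifnot(inherits(genome, "GenomeAssembly"))
  fams <- names(family_refs)
  census <- data.frame(family = character(), full = integer(),
                       partial = integer(), fragment = integer())
  hits_out <- data.frame(family = character(), seqid = character(),
                         start = integer(), end = integer(),
                         class = character())
  if (length(family_refs) == 0L) return(list(census = census, hits = hits_out))
  stopifnot(!is.null(fams), !anyDuplicated(fams))
  gfa <- tempfile("genome", fileext = ".fa")
  qfa <- tempfile("refs", fileext = ".fa")
  write_fasta(genome, gfa)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(family_refs), qfa)
  bl <- run_blastn(gfa, qfa, perc_identity = 100 * min_identity)
  for (fam in fams) {
    h <- bl[bl$qseqid == fam, , drop = FALSE]
    full <- partial <- fragment <- 0L
    if (nrow(h)) {
      s0 <- pmin(h$sstart, h$send) - 1L    # to 0-based half-open
      e0 <- pmax(h$sstart, h$send)
      gr <- GenomicRanges::GRanges(h$sseqid,
                                   IRanges::IRanges(start = s0 + 1L, end = e0))
      # an element's two LTRs cross-match, producing short HSPs nested in
      # the full-length HSP that can nudge merged boundaries; drop HSPs
      # mostly covered by a longer kept HSP before merging
      gr <- gr[order(-GenomicRanges::width(gr))]
      keep_hsp <- rep(TRUE, length(gr))
      for (ii in seq_along(gr)) {
        if (ii == 1L) next
        prior <- gr[which(keep_hsp[seq_len(ii - 1L)])]
        ov <- GenomicRanges::intersect(
          GenomicRanges::reduce(prior), gr[ii], ignore.strand = TRUE)
        if (sum(GenomicRanges::width(ov)) >=
            0.5 * GenomicRanges::width(gr[ii])) keep_hsp[ii] <- FALSE
      }
      gr <- GenomicRanges::reduce(gr[keep_hsp])
      w <- GenomicRanges::width(gr)
      cls <- rep(NA_character_, length(gr))
      cls[w >= full_length_fraction * nchar(family_refs[[fam]])] <- "full"
      cls[is.na(cls) & w > partial_min] <- "partial"
      cls[is.na(cls) & w >= fragment_min] <- "fragment"
      keep <- !is.na(cls)
      if (any(keep)) {
        hits_out <- rbind(hits_out, data.frame(
          family = fam,
          seqid = as.character(GenomicRanges::seqnames(gr))[keep],
          start = GenomicRanges::start(gr)[keep] - 1L,
          end = GenomicRanges::end(gr)[keep],
          class = cls[keep]
        ))
        full <- sum(cls[keep] == "full")
        partial <- sum(cls[keep] == "partial")
        fragment <- sum(cls[keep] == "fragment")
      }
    }
    census <- rbind(census, data.frame(family = fam, full = full,
                                       partial = partial, fragment = fragment))
  }
  rownames(census) <- rownames(hits_out) <- NULL
  list(census = census, hits = hits_out)
}
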