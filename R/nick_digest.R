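# In-silico nicking-enzyme digest and tandem-period detection, used to
# localize large tandem repeats (e.g. rDNA arrays) from label patterns.

#' Nt.BspQI recognition sequence
#' @export
NT_BSPQI_MOTIF <- "GCTCTTC"

#' Virtual single-strand nickase digest
#'
#' Reports every occurrence of `motif` and of its reverse complement in
#' `sequence`, with the strand carrying the recognition site. Overlapping
#' occurrences are all reported. A nicking enzyme cuts one strand, so the
#' two strands are reported separately; a minimum inter-site distance can
#' optionally thin near-coincident sites the way close labels merge on an
#' imaged molecule.
#'
#' @param sequence DNA string.
#' @param motif Recognition sequence (length >= 4). Default [NT_BSPQI_MOTIF].
#' @param min_dist Minimum distance in bp between reported sites (0 keeps
#'   all sites).
#' @return A `NickSiteMap`: data.frame with 0-based `pos` (motif start) and
#'   `strand`, sorted by position.
#' @export
virtual_nick_digest <- function(sequence, motif = NT_BSPQI_MOTIF, min_dist = 0L) {
  stopifnot(nchar(motif) >= 4L)
  if (nchar(sequence) == 0L) {
    return(data.frame(pos = integer(), strand = character()))
  }
  subj <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::start(Biostrings::matchPattern(motif, subj)) - 1L
  rev <- Biostrings::start(Biostrings::matchPattern(revcomp(motif), subj)) - 1L
  df <- data.frame(
    pos = c(fwd, rev),
    strand = c(rep("+", length(fwd)), rep("-", length(rev)))
  )
  df <- df[order(df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  if (min_dist > 0L && nrow(df) > 1L) {
    keep <- logical(nrow(df))
    last <- -Inf
    for (i in seq_len(nrow(df))) {
      if (df$pos[i] - last >= min_dist) {
        keep[i] <- TRUE
        last <- df$pos[i]
      }
    }
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Dominant tandem period of a nick-site pattern
#'
#' Estimates the unit length of a tandem array from the strand-merged site
#' positions. Candidate periods are taken from pairwise site spacings; a
#' candidate is supported by every chain of sites `s, s+p, s+2p, ...`
#' (within a small tolerance). A period is reported only when some chain
#' spans at least three sites (three consecutive repeats of the unit) and
#' total support is at least three chain links; otherwise `NULL`.
#'
#' @param sitemap A `NickSiteMap` from [virtual_nick_digest].
#' @param window Optional `c(start, end)` restricting sites to an interval.
#' @param min_period Smallest unit length considered, bp.
#' @param tol_frac Matching tolerance as a fraction of the candidate period
#'   (at least 2 bp, at most `tol_max`).
#' @param tol_max Absolute cap on the matching tolerance, bp.
#' @param min_explained Minimum fraction of the (windowed) sites that must
#'   belong to chains of the candidate period; random site patterns contain
#'   occasional short arithmetic progressions but never explain most sites.
#' @return `NULL`, or a list with `period` (bp, mean chained spacing),
#'   `support` (number of chain links), `explained` (fraction of sites in
#'   chains) and `n_sites`.
#' @export
detect_tandem_period <- function(sitemap, window = NULL, min_period = 500,
                                 tol_frac = 0.002, tol_max = 25,
                                 min_explained = 0.5) {
  pos <- sort(unique(sitemap$pos))
  if (!is.null(window)) pos <- pos[pos >= window[1] & pos < window[2]]
  n <- length(pos)
  if (n < 6L) return(NULL)
  d <- outer(pos, pos, "-")
  cand <- sort(unique(d[d >= min_period]))
  if (!length(cand)) return(NULL)
  best <- NULL
  for (p in cand) {
    tol <- min(max(2, round(tol_frac * p)), tol_max)
    links <- 0L
    longest <- 0L
    steps <- numeric()
    in_chain <- logical(n)
    used <- logical(n)
    for (i in seq_len(n)) {
      if (used[i]) next
      chain <- 0L
      cur <- i
      repeat {
        nxt <- which(abs(pos - (pos[cur] + p)) <= tol)
        if (!length(nxt)) break
        nxt <- nxt[which.min(abs(pos[nxt] - (pos[cur] + p)))]
        steps <- c(steps, pos[nxt] - pos[cur])
        chain <- chain + 1L
        in_chain[c(cur, nxt)] <- TRUE
        used[nxt] <- TRUE
        cur <- nxt
      }
      links <- links + chain
      longest <- max(longest, chain)
    }
    explained <- mean(in_chain)
    if (longest >= 2L && links >= 3L && explained >= min_explained) {
      if (is.null(best) || links > best$support) {
        best <- list(period = mean(steps), support = links,
                     explained = explained, n_sites = n)
      }
    }
  }
  best
}

#' Export a nick-site map as 6-column BED
#'
#' @param sitemap A `NickSiteMap`.
#' @param chrom Chromosome id for the BED records.
#' @param path Output path.
#' @param motif_len Motif length (sets BED interval width).
#' @return `path`, invisibly.
#' @export
write_nicksites_bed <- function(sitemap, chrom, path,
                                motif_len = nchar(NT_BSPQI_MOTIF)) {
  bed <- data.frame(
    chrom = chrom,
    start = sitemap$pos,
    end = sitemap$pos + motif_len,
    name = sprintf("nick%05d", seq_len(nrow(sitemap))),
    score = 0L,
    strand = sitemap$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
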