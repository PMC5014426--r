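# Forward-strand ORF layout of an element. Elements are oriented by their
# LTR/TIR polarity before this scan, so only the three forward frames are
# read. An ORF is a maximal run of non-stop codons; its interval includes
# the terminating stop codon when one is present inside the sequence.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Annotate the ORF layout of an element
#'
#' Finds all maximal ORFs of at least `min_orf_aa` codons in the three
#' forward frames, orders them by start, and reports the spacer between
#' consecutive ORFs together with the number of in-frame stop codons each
#' spacer contains relative to the upstream ORF's frame (the upstream ORF's
#' own terminating stop is part of the ORF, not the spacer).
#'
#' @param element_seq Element sequence (>= 300 bp).
#' @param min_orf_aa Minimum ORF length in amino acids (non-stop codons).
#' @return A list with `orfs` (data.frame: `start`, `end` 0-based half-open,
#'   `length_aa`, `frame`), `spacer_lengths` and `spacer_stop_counts`.
#' @export
annotate_orf_layout <- function(element_seq, min_orf_aa = 100L) {
  n <- nchar(element_seq)
  stopifnot(n >= 300L)
  orfs <- list()
  stops_by_frame <- vector("list", 3L)
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    cod <- substring(element_seq, f + 1L + 3L * (seq_len(ncod) - 1L),
                     f + 3L * seq_len(ncod))
    is_stop <- cod %in% STOP_CODONS
    stops_by_frame[[f + 1L]] <- f + 3L * (which(is_stop) - 1L)  # 0-based codon starts
    r <- rle(is_stop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(!r$values & r$lengths >= min_orf_aa)
    for (i in runs) {
      s0 <- f + 3L * (starts[i] - 1L)
      e0 <- f + 3L * ends[i]
      has_stop <- ends[i] < ncod           # followed by an in-frame stop
      orfs[[length(orfs) + 1L]] <- data.frame(
        start = s0,
        end = if (has_stop) e0 + 3L else e0,
        length_aa = r$lengths[i],
        frame = f
      )
    }
  }
  if (!length(orfs)) {
    return(list(orfs = data.frame(start = integer(), end = integer(),
                                  length_aa = integer(), frame = integer()),
                spacer_lengths = integer(), spacer_stop_counts = integer()))
  }
  orfs <- do.call(rbind, orfs)
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  k <- nrow(orfs)
  sp_len <- integer(0)
  sp_stops <- integer(0)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      a_end <- orfs$end[i]
      b_start <- orfs$start[i + 1L]
      sp_len <- c(sp_len, b_start - a_end)
      st <- stops_by_frame[[orfs$frame[i] + 1L]]
      sp_stops <- c(sp_stops, sum(st >= a_end & st + 3L <= b_start))
    }
  }
  list(orfs = orfs, spacer_lengths = sp_len, spacer_stop_counts = sp_stops)
}
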