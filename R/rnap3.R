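# RNA polymerase III gene geometry: some Ty3/Gypsy elements integrate at
# RNAP3 transcription start sites; because the pre-tRNA carries a ~10-nt
# leader and insertion adds a short target-site duplication, element
# sequence typically lands 15-17 bp upstream of the mature tRNA-coding
# start. Dimeric RNAP3 genes are same-strand gene pairs separated by only a
# few nucleotides.

#' Classify the RNAP3-gene association of an insertion boundary
#'
#' @param insertion_point 0-based coordinate of the element's outer
#'   boundary nearest the candidate gene (a half-open end coordinate when
#'   the element lies upstream of a plus-strand gene).
#' @param rnap3_features Feature data.frame of RNAP3 genes on the same
#'   chromosome (tDNAs and 5S genes; strand required).
#' @param targeted_window Inclusive distance band (bp) upstream of the
#'   mature coding start that counts as start-targeted.
#' @param adjacent_window Distance (bp) within which an insertion is called
#'   adjacent.
#' @return One of `"rnap3-start-targeted"`, `"rnap3-internal"`,
#'   `"rnap3-adjacent"`, `"unassociated"`.
#' @export
classify_rnap3_association <- function(insertion_point, rnap3_features,
                                       targeted_window = c(15L, 17L),
                                       adjacent_window = 100L) {
  b <- insertion_point
  if (nrow(rnap3_features) == 0L) return("unassociated")
  cls <- "unassociated"
  rank <- c("unassociated" = 0, "rnap3-adjacent" = 1,
            "rnap3-start-targeted" = 2, "rnap3-internal" = 3)
  for (i in seq_len(nrow(rnap3_features))) {
    s <- rnap3_features$start[i]
    e <- rnap3_features$end[i]
    st <- rnap3_features$strand[i]
    this <- "unassociated"
    if (b >= s && b < e) {
      this <- "rnap3-internal"
    } else {
      d_up <- if (st == "-") b - e else s - b   # distance upstream of mature start
      if (!is.na(d_up) && d_up >= targeted_window[1] && d_up <= targeted_window[2]) {
        this <- "rnap3-start-targeted"
      } else if (min(abs(b - s), abs(b - e)) <= adjacent_window) {
        this <- "rnap3-adjacent"
      }
    }
    if (rank[[this]] > rank[[cls]]) cls <- this
  }
  cls
}

#' Detect dimeric RNAP3 gene pairs
#'
#' Adjacent same-strand RNAP3 genes whose inter-gene gap falls within
#' `[min_gap, max_gap]` bp are reported as ordered pairs (upstream member
#' first in transcription order).
#'
#' @param rnap3_features Feature data.frame of RNAP3 genes.
#' @param min_gap,max_gap Inclusive gap band in bp (defaults 5 and 26).
#' @return data.frame with `upstream_id`, `downstream_id`, `gap`, `seqid`,
#'   `strand`.
#' @export
detect_dimeric_rnap3 <- function(rnap3_features, min_gap = 5L, max_gap = 26L) {
  out <- data.frame(upstream_id = character(), downstream_id = character(),
                    gap = integer(), seqid = character(), strand = character())
  if (nrow(rnap3_features) < 2L) return(out)
  f <- rnap3_features[order(rnap3_features$seqid, rnap3_features$start), ,
                      drop = FALSE]
  for (i in seq_len(nrow(f) - 1L)) {
    a <- f[i, ]
    b <- f[i + 1L, ]
    if (a$seqid != b$seqid || a$strand != b$strand) next
    gap <- b$start - a$end
    if (gap >= min_gap && gap <= max_gap) {
      up_first <- a$strand != "-"
      out <- rbind(out, data.frame(
        upstream_id = if (up_first) a$id else b$id,
        downstream_id = if (up_first) b$id else a$id,
        gap = gap, seqid = a$seqid, strand = a$strand
      ))
    }
  }
  rownames(out) <- NULL
  out
}
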