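# Assembled anatomy of one element: run every structural detector on an
# element and its flanks and classify the insertion.

#' Annotate the full anatomy of one element
#'
#' Runs the TIR, TSD, LTR-pair, PBS, PPT and ORF detectors on an element
#' sequence and its flanks and classifies the element as full-length
#' (LTR pair present), solo-LTR (no LTR pair, length within the solo band),
#' partial (> 1 kb without an LTR pair) or fragment.
#'
#' @param element_seq Element sequence.
#' @param upstream_flank,downstream_flank Flanking sequence (for TSD
#'   detection); may be `NULL`.
#' @param trna_ends Named character vector of tRNA 3' ends for PBS search
#'   (may be empty).
#' @param family Optional family label.
#' @param params List of detector parameters (see defaults in code).
#' @return An `ElementAnatomy` list.
#' @export
annotate_element_anatomy <- function(element_seq, upstream_flank = NULL,
                                     downstream_flank = NULL,
                                     trna_ends = character(), family = NA,
                                     params = list()) {
  p <- utils::modifyList(list(
    max_tir_mismatch = 0L, tsd_min = 4L, tsd_max = 12L, tsd_offset_tol = 1L,
    tsd_max_mismatch = 0L, min_ltr = 100L, max_ltr = 1000L,
    ltr_min_identity = 0.90, pbs_min_match = 10L, pbs_window = 30L,
    ppt_min_run = 8L, ppt_window = 5L, min_orf_aa = 100L,
    solo_band = c(100L, 1000L)
  ), params)
  n <- nchar(element_seq)
  tir <- if (n >= 20L) {
    find_terminal_inverted_repeat(element_seq, p$max_tir_mismatch)
  } else NULL
  tsd <- if (!is.null(upstream_flank) && !is.null(downstream_flank) &&
             nchar(upstream_flank) >= p$tsd_max + p$tsd_offset_tol &&
             nchar(downstream_flank) >= p$tsd_max) {
    detect_tsd(upstream_flank, downstream_flank, p$tsd_min, p$tsd_max,
               p$tsd_offset_tol, p$tsd_max_mismatch)
  } else NULL
  ltr <- if (n >= 2L * p$min_ltr) {
    find_ltr_pair(element_seq, p$min_ltr, p$max_ltr, p$ltr_min_identity)
  } else NULL
  pbs <- ppt <- orf <- NULL
  if (!is.null(ltr)) {
    internal <- s_sub(element_seq, ltr$ltr5[2], ltr$ltr3[1])
    if (nchar(internal) >= p$pbs_min_match) {
      pbs <- find_pbs(internal, trna_ends, p$pbs_min_match, p$pbs_window)
      ppt <- find_ppt(internal, p$ppt_min_run, p$ppt_window)
    }
    if (n >= 300L) orf <- annotate_orf_layout(element_seq, p$min_orf_aa)
  }
  classification <- if (!is.null(ltr)) {
    "full-length"
  } else if (n >= p$solo_band[1] && n <= p$solo_band[2]) {
    "solo-LTR"
  } else if (n > 1000L) "partial" else "fragment"
  structure(list(
    family = family, length = n, tir = tir, tsd = tsd, ltr_pair = ltr,
    pbs = pbs, ppt = ppt, orf_layout = orf, classification = classification
  ), class = "ElementAnatomy")
}

#' @export
print.ElementAnatomy <- function(x, ...) {
  cat("ElementAnatomy:", x$classification, sprintf("(%d bp)", x$length), "\n")
  if (!is.null(x$tir)) cat("  TIR", x$tir$length, "bp",
                           if (x$tir$conforming) "(TG...CA)" else "", "\n")
  if (!is.null(x$tsd)) cat("  TSD", x$tsd$length, "bp, offset", x$tsd$offset, "\n")
  if (!is.null(x$ltr_pair)) cat("  LTR pair", x$ltr_pair$ltr_length, "bp, identity",
                                round(x$ltr_pair$identity, 3), "\n")
  if (!is.null(x$pbs)) cat("  PBS", x$pbs$match_length, "nt at +",
                           x$pbs$start_offset, " (", x$pbs$trna_id, ")\n", sep = "")
  if (!is.null(x$ppt)) cat("  PPT", x$ppt$run_length, "purines, end offset",
                           x$ppt$end_offset, "\n")
  if (!is.null(x$orf_layout) && nrow(x$orf_layout$orfs))
    cat("  ORFs:", nrow(x$orf_layout$orfs), "; spacers:",
        paste(x$orf_layout$spacer_lengths, collapse = ","), "\n")
  invisible(x)
}

#' Export element anatomies as GFF3
#'
#' One parent feature per element with SO-style child features for the
#' LTRs, PBS, PPT, ORFs and TSD.
#'
#' @param anatomies List of `ElementAnatomy` objects.
#' @param intervals data.frame with `seqid`, `start`, `end` (0-based
#'   half-open genomic interval of each element).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anatomy_gff3 <- function(anatomies, intervals, path) {
  stopifnot(length(anatomies) == nrow(intervals))
  rows <- list()
  for (i in seq_along(anatomies)) {
    an <- anatomies[[i]]
    s <- intervals$start[i]
    sq <- intervals$seqid[i]
    pid <- sprintf("TE%04d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = sq, start = s, end = intervals$end[i], strand = "+",
      kind = "TE", family = as.character(an$family %||% NA), id = pid,
      type = "mobile_genetic_element")
    child <- function(cs, ce, type, suffix) data.frame(
      seqid = sq, start = s + cs, end = s + ce, strand = "+", kind = "other",
      family = NA_character_, id = paste0(pid, "_", suffix), type = type)
    if (!is.null(an$ltr_pair)) {
      rows[[length(rows) + 1L]] <- child(an$ltr_pair$ltr5[1], an$ltr_pair$ltr5[2],
                                         "long_terminal_repeat", "LTR5")
      rows[[length(rows) + 1L]] <- child(an$ltr_pair$ltr3[1], an$ltr_pair$ltr3[2],
                                         "long_terminal_repeat", "LTR3")
      if (!is.null(an$pbs)) {
        ps <- an$ltr_pair$ltr5[2] + an$pbs$start_offset
        rows[[length(rows) + 1L]] <- child(ps, ps + an$pbs$match_length,
                                           "primer_binding_site", "PBS")
      }
      if (!is.null(an$ppt)) {
        pe <- an$ltr_pair$ltr3[1] - an$ppt$end_offset
        rows[[length(rows) + 1L]] <- child(pe - an$ppt$run_length, pe,
                                           "RR_tract", "PPT")
      }
      if (!is.null(an$orf_layout) && nrow(an$orf_layout$orfs)) {
        for (k in seq_len(nrow(an$orf_layout$orfs))) {
          rows[[length(rows) + 1L]] <- child(an$orf_layout$orfs$start[k],
                                             an$orf_layout$orfs$end[k],
                                             "ORF", sprintf("ORF%d", k))
        }
      }
    }
  }
  feats <- do.call(rbind, rows)
  write_gff3(feats, path)
}
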