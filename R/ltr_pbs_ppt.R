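# LTR-pair, primer-binding-site and polypurine-tract detection: the
# replication signatures of LTR retrotransposons. A full-length element
# carries two near-identical long terminal repeats in direct orientation;
# minus-strand reverse transcription is primed by a tRNA annealed to the
# PBS just downstream of the 5' LTR, and plus-strand synthesis by a purine
# run (PPT) just upstream of the 3' LTR.

#' Find a directly repeated LTR pair at the element termini
#'
#' Aligns the first and last `max_ltr` bp of the element with an affine-gap
#' local alignment and reports the best pair of near-identical terminal
#' repeats. LTR boundaries are the maximal local-alignment extension at the
#' scoring used (match +2, mismatch -3, gap open 5, gap extend 2), so a
#' terminal substitution trims at most two bases.
#'
#' @param element_seq Element sequence (>= 2 * `min_ltr` bp).
#' @param min_ltr,max_ltr LTR length band searched (bp).
#' @param min_identity Minimum identity (matches / aligned base pairs).
#' @return `NULL`, or a list with `ltr5`, `ltr3` (0-based half-open
#'   element-relative intervals), `identity` and `ltr_length`.
#' @export
find_ltr_pair <- function(element_seq, min_ltr = 100L, max_ltr = 1000L,
                          min_identity = 0.90) {
  n <- nchar(element_seq)
  stopifnot(n >= 2L * min_ltr)
  w <- min(max_ltr, n %/% 2L)   # disjoint windows by construction
  head <- s_sub(element_seq, 0L, w)
  tail <- s_sub(element_seq, n - w, n)
  pa <- Biostrings::pairwiseAlignment(
    head, tail, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2
  )
  pr <- pa@pattern@range
  sr <- pa@subject@range
  len5 <- IRanges::width(pr)
  len3 <- IRanges::width(sr)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  identity <- if (nm + nmm > 0) nm / (nm + nmm) else 0
  if (len5 < min_ltr || len3 < min_ltr) return(NULL)
  if (abs(len5 - len3) > 2L) return(NULL)
  if (identity < min_identity) return(NULL)
  ltr5 <- c(IRanges::start(pr) - 1L, IRanges::end(pr))
  ltr3 <- c(n - w + IRanges::start(sr) - 1L, n - w + IRanges::end(sr))
  if (ltr5[2] > ltr3[1]) return(NULL)
  list(ltr5 = ltr5, ltr3 = ltr3, identity = identity,
       ltr_length = as.integer(round((len5 + len3) / 2)))
}

#' Find the primer binding site downstream of the 5' LTR
#'
#' Searches the region just downstream of the upstream LTR for the best
#' reverse-complement match to the 3' terminus of any provided tRNA (the
#' minus-strand primer). Best is the longest match, ties broken by
#' proximity to the LTR.
#'
#' @param internal_seq Sequence immediately downstream of the 5' LTR.
#' @param trna_three_prime_ends Named character vector of tRNA 3'-end
#'   sequences (DNA alphabet; at least `min_match` bases each).
#' @param min_match Minimum complementary match length (bp).
#' @param search_window The match must start within this many bp of the LTR.
#' @param allow_wobble Also accept G:T (G:U-equivalent) pairings.
#' @return `NULL`, or a list with `start_offset` (bp downstream of the LTR
#'   end), `match_length` and `trna_id`.
#' @export
find_pbs <- function(internal_seq, trna_three_prime_ends, min_match = 10L,
                     search_window = 30L, allow_wobble = FALSE) {
  if (length(trna_three_prime_ends) == 0L) return(NULL)
  seq <- s_chars(internal_seq)
  n <- length(seq)
  best <- NULL
  for (id in names(trna_three_prime_ends)) {
    t3 <- s_chars(trna_three_prime_ends[[id]])
    m <- length(t3)
    for (s in 0:min(search_window, n - min_match)) {
      k <- 0L
      while (k < m && s + k < n) {
        b <- seq[s + k + 1L]
        tb <- t3[m - k]
        pair <- b == COMP[tb] ||
          (allow_wobble && ((b == "T" && tb == "G") || (b == "G" && tb == "T")))
        if (!pair) break
        k <- k + 1L
      }
      if (k >= min_match &&
          (is.null(best) || k > best$match_length ||
           (k == best$match_length && s < best$start_offset))) {
        best <- list(start_offset = s, match_length = k, trna_id = id)
      }
    }
  }
  best
}

#' Find the polypurine tract upstream of the 3' LTR
#'
#' Reports the longest run of purines (A/G) that ends within
#' `search_window` bp of the downstream LTR.
#'
#' @param internal_tail_seq Sequence immediately upstream of the 3' LTR
#'   (its last base abuts the LTR).
#' @param min_run Minimum run length (bp).
#' @param search_window Maximum distance (bp) between the run end and the
#'   LTR.
#' @return `NULL`, or a list with `run_length`, `end_offset` (bp upstream
#'   of the LTR start) and `seq`.
#' @export
find_ppt <- function(internal_tail_seq, min_run = 8L, search_window = 5L) {
  n <- nchar(internal_tail_seq)
  if (n == 0L) return(NULL)
  isp <- s_chars(internal_tail_seq) %in% c("A", "G")
  r <- rle(isp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pur <- which(r$values)
  if (!length(pur)) return(NULL)
  cand <- pur[(n - ends[pur]) <= search_window & r$lengths[pur] >= min_run]
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  list(
    run_length = r$lengths[best],
    end_offset = n - ends[best],
    seq = s_sub(internal_tail_seq, starts[best] - 1L, ends[best])
  )
}
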