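# Terminal inverted repeats and target-site duplications: the two
# sequence signatures that delimit a transposable-element insertion.
# Integrases recognize inverted element termini (minimally TG...CA), and
# repair of the staggered strand-transfer cut duplicates a short stretch of
# target DNA on both sides of the new insertion.

#' Longest terminal inverted repeat of an element
#'
#' Compares the element's 5' terminus with the reverse complement of its 3'
#' terminus at every length and returns the longest with at most
#' `max_mismatch` mismatches. An `N` opposite anything counts as a
#' mismatch. The result is flagged `conforming` when the termini match the
#' near-universal TG...CA rule.
#'
#' @param element_seq Element sequence (>= 20 bp).
#' @param max_mismatch Mismatches tolerated in the repeat.
#' @param min_len Shortest repeat reported.
#' @return `NULL`, or a list with `length`, `left_seq`, `right_seq`,
#'   `mismatches`, `conforming`.
#' @export
find_terminal_inverted_repeat <- function(element_seq, max_mismatch = 0L,
                                          min_len = 2L) {
  n <- nchar(element_seq)
  stopifnot(n >= 20L)
  maxl <- n %/% 2L
  left <- s_chars(s_sub(element_seq, 0L, maxl))
  right <- s_chars(s_sub(element_seq, n - maxl, n))
  # mm[L]: mismatches between prefix of length L and revcomp of suffix of L
  rc <- comp_bases(rev(right))          # rc[i] pairs with left[i]
  neq <- left != rc | left == "N" | rc == "N"
  mm <- cumsum(neq)
  ok <- which(mm[min_len:maxl] <= max_mismatch) + (min_len - 1L)
  if (!length(ok)) return(NULL)
  L <- max(ok)
  ls <- s_sub(element_seq, 0L, L)
  rs <- s_sub(element_seq, n - L, n)
  list(
    length = L, left_seq = ls, right_seq = rs,
    mismatches = unname(mm[L]),
    conforming = startsWith(ls, "TG") && endsWith(rs, "CA")
  )
}

#' Detect a target-site duplication around an insertion
#'
#' Looks for the longest word whose copy ends the upstream flank and begins
#' the downstream flank. The upstream copy may sit up to `offset_tol` bases
#' before the element boundary (the published worked case has the upstream
#' copy offset by one base). Ties are broken by longer length, then smaller
#' offset.
#'
#' @param upstream_flank Sequence immediately 5' of the element (its last
#'   bases abut the element start).
#' @param downstream_flank Sequence immediately 3' of the element.
#' @param min_len,max_len Length band searched.
#' @param offset_tol Maximum shift (bp) of the upstream copy away from the
#'   element boundary.
#' @param max_mismatch Mismatches tolerated between the two copies.
#' @return `NULL`, or a list with `length`, `upstream_copy`,
#'   `downstream_copy`, `offset`, `mismatches`.
#' @export
detect_tsd <- function(upstream_flank, downstream_flank, min_len = 4L,
                       max_len = 12L, offset_tol = 1L, max_mismatch = 0L) {
  nu <- nchar(upstream_flank)
  nd <- nchar(downstream_flank)
  stopifnot(nu >= max_len + offset_tol, nd >= max_len)
  for (L in seq(max_len, min_len)) {
    down <- s_chars(s_sub(downstream_flank, 0L, L))
    for (o in 0L:offset_tol) {
      up <- s_chars(s_sub(upstream_flank, nu - L - o, nu - o))
      mm <- sum(up != down | up == "N" | down == "N")
      if (mm <= max_mismatch) {
        return(list(
          length = L,
          upstream_copy = paste(up, collapse = ""),
          downstream_copy = paste(down, collapse = ""),
          offset = o, mismatches = mm
        ))
      }
    }
  }
  NULL
}
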