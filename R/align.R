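# Global affine-gap pairwise alignment of allelic locus sequences, and the
# mismatch / inserted-base / deleted-base accounting derived from it.
# Scoring defaults mimic a glocal cDNA-style aligner: match +1,
# mismatch -2, gap open -6, gap extend -1.

default_align_params <- function() {
  list(match = 1, mismatch = -2, gap_open = 6, gap_extend = 1,
       length_cap = 50000L, anchor_k = 32L)
}

align_global_direct <- function(seq_a, seq_b, p) {
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = p$match, mismatch = p$mismatch, baseOnly = FALSE),
    gapOpening = p$gap_open, gapExtension = p$gap_extend
  )
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# find a shared unique k-mer near the middle of A to split long problems
find_split_anchor <- function(seq_a, seq_b, k) {
  na <- nchar(seq_a)
  mid <- na %/% 2L
  offsets <- c(0L, -k, k, -2L * k, 2L * k, -4L * k, 4L * k, -8L * k, 8L * k)
  for (off in offsets) {
    s <- mid + off
    if (s < 0L || s + k > na) next
    kmer <- s_sub(seq_a, s, s + k)
    if (grepl("N", kmer, fixed = TRUE)) next
    hits_b <- Biostrings::start(Biostrings::matchPattern(kmer,
                                                         Biostrings::DNAString(seq_b)))
    if (length(hits_b) != 1L) next
    hits_a <- Biostrings::start(Biostrings::matchPattern(kmer,
                                                         Biostrings::DNAString(seq_a)))
    if (length(hits_a) != 1L) next
    return(c(a = s, b = hits_b - 1L))
  }
  NULL
}

align_global_rec <- function(seq_a, seq_b, p) {
  if (max(nchar(seq_a), nchar(seq_b)) <= p$length_cap) {
    return(align_global_direct(seq_a, seq_b, p))
  }
  anc <- find_split_anchor(seq_a, seq_b, p$anchor_k)
  if (is.null(anc)) return(align_global_direct(seq_a, seq_b, p))
  k <- p$anchor_k
  left <- align_global_rec(s_sub(seq_a, 0L, anc[["a"]]),
                           s_sub(seq_b, 0L, anc[["b"]]), p)
  right <- align_global_rec(s_sub(seq_a, anc[["a"]] + k, nchar(seq_a)),
                            s_sub(seq_b, anc[["b"]] + k, nchar(seq_b)), p)
  kmer <- s_sub(seq_a, anc[["a"]], anc[["a"]] + k)
  list(a = paste0(left$a, kmer, right$a),
       b = paste0(left$b, kmer, right$b),
       score = left$score + right$score + k * p$match)
}

#' Globally align two locus sequences
#'
#' Deterministic global affine-gap alignment. Pairs longer than
#' `length_cap` are split at a shared unique anchor k-mer and the parts
#' aligned recursively.
#'
#' @param seq_a,seq_b Sequences (strain A and strain B).
#' @param params Scoring parameters; see `default_align_params` defaults in
#'   code (match +1, mismatch -2, gap open 6, gap extend 1, cap 50 kb).
#' @return A `PairwiseAlignment` list: gapped strings `a_aln`, `b_aln`,
#'   operation string `ops` over M (match), X (mismatch), I (base present
#'   in A only), D (base present in B only), plus `identity` (matches /
#'   aligned base pairs, N columns excluded), `coverage_a`, `coverage_b`
#'   and `score`.
#' @export
align_pair <- function(seq_a, seq_b, params = list()) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) stop("empty sequence")
  p <- utils::modifyList(default_align_params(), params)
  al <- align_global_rec(toupper(seq_a), toupper(seq_b), p)
  ac <- s_chars(al$a)
  bc <- s_chars(al$b)
  ops <- character(length(ac))
  ops[ac == "-"] <- "D"
  ops[bc == "-"] <- "I"
  both <- ac != "-" & bc != "-"
  ops[both & ac == bc] <- "M"
  ops[both & ac != bc] <- "X"
  hasN <- ac == "N" | bc == "N"
  ops[both & hasN] <- ifelse(ac[both & hasN] == bc[both & hasN], "M", "X")
  nm <- sum(ops == "M" & !hasN)
  nx <- sum(ops == "X" & !hasN)
  list(
    a_aln = al$a, b_aln = al$b, ops = paste(ops, collapse = ""),
    identity = if (nm + nx > 0) nm / (nm + nx) else 0,
    coverage_a = sum(both) / nchar(seq_a),
    coverage_b = sum(both) / nchar(seq_b),
    score = al$score
  )
}

#' Count variants in a pairwise alignment
#'
#' Mismatch columns, bases present in A but unaligned in B (insertions) and
#' bases present in B but unaligned in A (deletions); any column involving
#' an N is excluded from all three counts, so assembly gaps do not inflate
#' variant counts. Terminal gap runs (the overhang of a glocal pair of
#' unequal loci) and gap runs longer than `max_structural` bp are locus
#' structure — an element insertion or a split locus, not small-indel
#' divergence — and are excluded from the indel counts.
#'
#' @param alignment Result of [align_pair].
#' @param max_structural Longest gap run (bp) still counted as an indel
#'   variant.
#' @return List with `mismatches`, `inserted_bases`, `deleted_bases`, and
#'   auxiliary event counts `insertion_events`, `deletion_events`.
#' @export
count_variants <- function(alignment, max_structural = 100L) {
  ac <- s_chars(alignment$a_aln)
  bc <- s_chars(alignment$b_aln)
  ops <- s_chars(alignment$ops)
  # terminal gap runs are locus-structure overhang (glocal semantics), not
  # sequence variants: trim them before counting
  aligned <- which(ops %in% c("M", "X"))
  if (length(aligned) && (aligned[1L] > 1L ||
                          aligned[length(aligned)] < length(ops))) {
    keep <- seq(aligned[1L], aligned[length(aligned)])
    ac <- ac[keep]
    bc <- bc[keep]
    ops <- ops[keep]
  }
  hasN <- ac == "N" | bc == "N"
  runs <- rle(ops)
  ends <- cumsum(runs$lengths)
  structural <- logical(length(ops))
  big <- which(runs$values %in% c("I", "D") & runs$lengths > max_structural)
  for (i in big) structural[(ends[i] - runs$lengths[i] + 1L):ends[i]] <- TRUE
  ins <- ops == "I" & !hasN & !structural
  del <- ops == "D" & !hasN & !structural
  list(
    mismatches = sum(ops == "X" & !hasN),
    inserted_bases = sum(ins),
    deleted_bases = sum(del),
    insertion_events = sum(runs$values == "I" &
                             runs$lengths <= max_structural),
    deletion_events = sum(runs$values == "D" & runs$lengths <= max_structural)
  )
}

#' Variant density per kb
#'
#' Densities are anchored on the strain-A iLocus length so that insertion
#' and deletion densities are comparable across pairs.
#'
#' @param counts Result of [count_variants].
#' @param ilocus_a_length Strain-A iLocus length in bp (> 0).
#' @return List with `M`, `I`, `D` (per kb) and `denominator_kb`.
#' @export
variant_density <- function(counts, ilocus_a_length) {
  if (ilocus_a_length <= 0) stop("ilocus_a_length must be positive")
  kb <- ilocus_a_length / 1000
  list(M = counts$mismatches / kb, I = counts$inserted_bases / kb,
       D = counts$deleted_bases / kb, denominator_kb = kb)
}
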