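# Solo-LTR family clustering. Recombination between the two LTRs of a
# full-length element deletes the internal domain and one LTR, leaving a
# solo LTR; families of related solo LTRs are recovered by single-linkage
# clustering on pairwise sequence identity, with a majority-rule consensus
# per family.

pairwise_identity_global <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 6, gapExtension = 1
  )
  # coverage-weighted: matches over the longer sequence
  Biostrings::nmatch(pa) / max(nchar(a), nchar(b))
}

#' Cluster solo-LTR candidates into families
#'
#' Single-linkage clustering at pairwise coverage-weighted identity
#' (matches over the longer sequence) of at least `identity_threshold`.
#' Each family carries a majority-rule consensus (columns of a per-member
#' global alignment to the family's longest member) and the mean member
#' length.
#'
#' @param candidate_seqs Named character vector of candidate solo-LTR
#'   sequences (100-1000 bp each).
#' @param identity_threshold Clustering identity threshold.
#' @return List of families, each a list with `family_id`, `members`
#'   (names), `consensus`, `mean_length`.
#' @export
cluster_solo_ltrs <- function(candidate_seqs, identity_threshold = 0.80) {
  n <- length(candidate_seqs)
  if (n == 0L) return(list())
  if (is.null(names(candidate_seqs))) {
    names(candidate_seqs) <- sprintf("ltr%03d", seq_len(n))
  }
  stopifnot(all(nchar(candidate_seqs) >= 100L),
            all(nchar(candidate_seqs) <= 1000L))
  # union-find single linkage
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (findp(i) == findp(j)) next
        if (pairwise_identity_global(candidate_seqs[[i]],
                                     candidate_seqs[[j]]) >= identity_threshold) {
          parent[findp(j)] <- findp(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), findp, integer(1L))
  fams <- split(seq_len(n), roots)
  out <- vector("list", length(fams))
  for (k in seq_along(fams)) {
    idx <- fams[[k]]
    seqs <- candidate_seqs[idx]
    ref <- seqs[[which.max(nchar(seqs))]]
    cols <- matrix(NA_character_, nrow = length(seqs), ncol = nchar(ref))
    for (m in seq_along(seqs)) {
      if (seqs[[m]] == ref) {
        cols[m, ] <- s_chars(ref)
        next
      }
      pa <- Biostrings::pairwiseAlignment(
        seqs[[m]], ref, type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -2, baseOnly = FALSE),
        gapOpening = 6, gapExtension = 1
      )
      qa <- s_chars(as.character(Biostrings::alignedPattern(pa)))
      ra <- s_chars(as.character(Biostrings::alignedSubject(pa)))
      ref_col <- cumsum(ra != "-")
      keep <- ra != "-" & qa != "-"
      cols[m, ref_col[keep]] <- qa[keep]
    }
    consensus <- apply(cols, 2L, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) return("N")
      tb <- sort(table(col), decreasing = TRUE)
      names(tb)[1L]
    })
    out[[k]] <- list(
      family_id = sprintf("soloLTR_fam%02d", k),
      members = names(seqs),
      consensus = paste(consensus, collapse = ""),
      mean_length = mean(nchar(seqs))
    )
  }
  out
}
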