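# Flanking-density contrast between allelic and non-allelic elements.
# Elements inherited through a cross sit in flanking sequence whose
# divergence matches its parental origin; elements that transposed after
# the cross land in sequence of average divergence. Averaging variant
# densities over the iLoci surrounding each insertion and contrasting
# allelic against non-allelic elements separates the two histories.

#' Per-TE flanking variant-density profile
#'
#' For each TE, the unweighted mean of the M, I and D densities over its
#' flanking iLoci that have allelic partners. Flanks without partners
#' contribute nothing and reduce `n_flanks`; TEs with no usable flank are
#' dropped with a warning.
#'
#' @param te_table Feature data.frame of TEs with an `allelism` column
#'   (`"allelic"`/`"non-allelic"`).
#' @param flanksets Named list of `FlankSet`s keyed by TE id.
#' @param pairs Pair table from [reciprocal_map] (carries M/I/D per pair).
#' @return data.frame with `te_id`, `family`, `allelism`, `mean_M`,
#'   `mean_I`, `mean_D`, `n_flanks`.
#' @export
flank_density_profile <- function(te_table, flanksets, pairs) {
  rows <- list()
  dropped <- character()
  for (i in seq_len(nrow(te_table))) {
    te_id <- te_table$id[i]
    fs <- flanksets[[te_id]]
    if (is.null(fs)) next
    ids <- c(fs$upstream, fs$downstream)
    j <- match(ids, pairs$a_id)
    j <- j[!is.na(j)]
    if (!length(j)) {
      dropped <- c(dropped, te_id)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      te_id = te_id, family = te_table$family[i],
      allelism = te_table$allelism[i],
      mean_M = mean(pairs$M[j]), mean_I = mean(pairs$I[j]),
      mean_D = mean(pairs$D[j]), n_flanks = length(j)
    )
  }
  if (length(dropped)) {
    warning("dropped TE(s) with no usable flank: ",
            paste(dropped, collapse = ", "))
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    te_id = character(), family = character(), allelism = character(),
    mean_M = numeric(), mean_I = numeric(), mean_D = numeric(),
    n_flanks = integer())
  rownames(out) <- NULL
  out
}

#' Permutation test for a difference of group mean densities
#'
#' Two-sided label-permutation p-value for the difference of group means,
#' `(count + 1) / (n_perm + 1)` convention, with a Wilcoxon rank-sum
#' p-value reported alongside as a distribution-free cross-check.
#'
#' @param records_a,records_b Profile data.frames from
#'   [flank_density_profile] for the two groups (each >= 2 rows).
#' @param metric `"M"`, `"I"` or `"D"`.
#' @param n_perm Number of label permutations.
#' @param seed RNG seed (results are reproducible for a fixed seed).
#' @return A `GroupComparison` list: `statistic` (mean of group a minus
#'   mean of group b), `p_value`, `p_ranksum`, `n_perm`, `seed`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(records_a, records_b, metric = c("M", "I", "D"),
                           n_perm = 10000L, seed = 1L) {
  metric <- match.arg(metric)
  col <- paste0("mean_", metric)
  va <- records_a[[col]]
  vb <- records_b[[col]]
  if (length(va) < 2L || length(vb) < 2L) {
    stop("each group needs at least 2 records")
  }
  obs <- mean(va) - mean(vb)
  pool <- c(va, vb)
  n1 <- length(va)
  n <- length(pool)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n, n1)
    mean(pool[idx]) - mean(pool[-idx])
  }, numeric(1L))
  p <- (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  pr <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE)$p.value)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(statistic = obs, p_value = p, p_ranksum = pr, n_perm = n_perm,
       seed = seed, n_a = length(va), n_b = length(vb))
}

#' Three-hypothesis inheritance report
#'
#' Summarizes, per TE family and pooled, the allelic / non-allelic counts,
#' group flank-density means and permutation p-values, and the fraction of
#' naive sites found empty in the partner genome. The verdict fields
#' follow the logic of the analysis: degenerated-ancient-relic (H1) is
#' excluded when reconstructed naive sites are found empty in the partner
#' genome; differential segregation from the cross (H2) is supported when
#' non-allelic elements sit in significantly denser flanking variation
#' than allelic ones; otherwise the data are consistent with post-cross
#' transposition into average sequence (H3).
#'
#' @param profiles Output of [flank_density_profile].
#' @param empty_sites Optional data.frame with `te_id`, `found` (logical)
#'   from [locate_empty_site] runs.
#' @param baselines Optional named list of genome-wide density baselines
#'   (echoed into the report).
#' @param alpha Significance threshold for the H2 verdict.
#' @param n_perm,seed Passed to [compare_groups].
#' @return A report list (families, pooled comparisons, verdicts).
#' @export
hypothesis_report <- function(profiles, empty_sites = NULL, baselines = NULL,
                              alpha = 0.05, n_perm = 10000L, seed = 1L) {
  fams <- unique(profiles$family)
  fam_rows <- list()
  for (fam in fams) {
    pf <- profiles[profiles$family == fam, , drop = FALSE]
    if (!nrow(pf)) {
      warning("family with no profile records omitted: ", fam)
      next
    }
    al <- pf[pf$allelism == "allelic", , drop = FALSE]
    na_ <- pf[pf$allelism == "non-allelic", , drop = FALSE]
    fam_rows[[fam]] <- data.frame(
      family = fam, n_allelic = nrow(al), n_non_allelic = nrow(na_),
      allelic_M = if (nrow(al)) mean(al$mean_M) else NA_real_,
      non_allelic_M = if (nrow(na_)) mean(na_$mean_M) else NA_real_,
      allelic_I = if (nrow(al)) mean(al$mean_I) else NA_real_,
      non_allelic_I = if (nrow(na_)) mean(na_$mean_I) else NA_real_,
      allelic_D = if (nrow(al)) mean(al$mean_D) else NA_real_,
      non_allelic_D = if (nrow(na_)) mean(na_$mean_D) else NA_real_
    )
  }
  families <- do.call(rbind, fam_rows)
  rownames(families) <- NULL
  al <- profiles[profiles$allelism == "allelic", , drop = FALSE]
  na_ <- profiles[profiles$allelism == "non-allelic", , drop = FALSE]
  comparisons <- list()
  if (nrow(al) >= 2L && nrow(na_) >= 2L) {
    for (m in c("M", "I", "D")) {
      comparisons[[m]] <- compare_groups(na_, al, m, n_perm = n_perm,
                                         seed = seed)
    }
  }
  frac_empty <- if (!is.null(empty_sites) && nrow(empty_sites)) {
    mean(empty_sites$found)
  } else NA_real_
  h1 <- if (is.na(frac_empty)) {
    "untested"
  } else if (frac_empty > 0) "excluded" else "not-excluded"
  h2h3 <- if (is.null(comparisons$M)) {
    "untested"
  } else if (comparisons$M$statistic > 0 && comparisons$M$p_value < alpha) {
    "H2-supported"
  } else "H3-consistent"
  list(
    families = families,
    pooled = list(
      n_allelic = nrow(al), n_non_allelic = nrow(na_),
      allelic_means = c(M = mean(al$mean_M), I = mean(al$mean_I),
                        D = mean(al$mean_D)),
      non_allelic_means = c(M = mean(na_$mean_M), I = mean(na_$mean_I),
                            D = mean(na_$mean_D)),
      comparisons = comparisons
    ),
    fraction_empty_sites = frac_empty,
    baselines = baselines,
    verdict = list(H1 = h1, H2_vs_H3 = h2h3)
  )
}
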