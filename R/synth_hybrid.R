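# Hybrid strain pair simulation: strain A descends from the ancestor;
# strain B is a haploid mosaic of ancestor-derived blocks and
# second-parent blocks carrying extra divergence. Ancestral elements are
# planted before the split and inherited by both strains; lineage elements
# are planted into one strain after its mutations, under their placement
# rule. The returned truth records every planted mutation class, block and
# element with per-strain coordinates and inheritance labels.

draw_parent2_blocks <- function(n, fraction, mean_len) {
  if (fraction <= 0) return(data.frame(start = integer(), end = integer()))
  if (fraction >= 1) return(data.frame(start = 0L, end = n))
  mean1 <- mean_len * (1 - fraction) / fraction
  blocks <- list()
  pos <- 0L
  state2 <- stats::runif(1L) < fraction
  while (pos < n) {
    len <- max(1000L, round(stats::rexp(1L, 1 / (if (state2) mean_len else mean1))))
    if (state2) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        start = pos, end = min(n, pos + len))
    }
    pos <- pos + len
    state2 <- !state2
  }
  if (!length(blocks)) return(data.frame(start = integer(), end = integer()))
  do.call(rbind, blocks)
}

plant_plan_into <- function(seqs, features, plan_rows, templates,
                            blocks_by_chrom = NULL, truth_prefix = "te",
                            truths = list(), block_margin = 5000L) {
  counter <- 0L
  for (r in seq_len(nrow(plan_rows))) {
    row <- plan_rows[r, ]
    tmpl <- templates[[row$family]]
    for (j in seq_len(row$count)) {
      counter <- counter + 1L
      te_id <- sprintf("%s_%s%03d", row$family, truth_prefix, counter)
      planted <- FALSE
      for (try in 1:25) {
        chrom <- sample(names(seqs), 1L,
                        prob = vapply(seqs, nchar, numeric(1L)))
        fch <- features[features$seqid == chrom, , drop = FALSE]
        p <- choose_site(nchar(seqs[[chrom]]), fch, row$placement,
                         blocks = blocks_by_chrom[[chrom]],
                         block_margin = if (try <= 15L) block_margin else 0L)
        if (is.na(p)) next
        res <- tryCatch(
          plant_element(seqs[[chrom]], fch, p, tmpl, te_id,
                        family = row$family),
          error = function(e) NULL)
        if (is.null(res)) next
        seqs[[chrom]] <- res$seq
        res$te$seqid <- chrom
        features <- rbind(features[features$seqid != chrom, , drop = FALSE],
                          res$features, res$te)
        features <- features[order(features$seqid, features$start), ,
                             drop = FALSE]
        # shift recorded block and truth coordinates on this chromosome
        ins_at <- p
        ins_len <- res$truth$tsd_len + res$truth$tsd_offset +
          res$truth$elem_len
        if (!is.null(blocks_by_chrom[[chrom]]) &&
            nrow(blocks_by_chrom[[chrom]])) {
          b <- blocks_by_chrom[[chrom]]
          b$start[b$start >= ins_at] <- b$start[b$start >= ins_at] + ins_len
          b$end[b$end > ins_at] <- b$end[b$end > ins_at] + ins_len
          blocks_by_chrom[[chrom]] <- b
        }
        for (k in seq_along(truths)) {
          tr <- truths[[k]]
          if (tr$chrom == chrom && tr$start >= ins_at) {
            truths[[k]]$start <- tr$start + ins_len
            truths[[k]]$end <- tr$end + ins_len
          }
        }
        truths[[te_id]] <- c(list(te_id = te_id, family = row$family,
                                  label = row$label,
                                  placement = row$placement, chrom = chrom),
                             res$truth)
        planted <- TRUE
        break
      }
      if (!planted) {
        stop("failed to place element ", te_id, " under rule ", row$placement)
      }
    }
  }
  rownames(features) <- NULL
  list(seqs = seqs, features = features, truths = truths,
       blocks_by_chrom = blocks_by_chrom)
}

remap_feature_df <- function(features, events_by_chrom) {
  for (chrom in names(events_by_chrom)) {
    ev <- events_by_chrom[[chrom]]
    if (!nrow(ev)) next
    sel <- features$seqid == chrom
    features$start[sel] <- remap_coords(features$start[sel], ev)
    features$end[sel] <- remap_coords(features$end[sel], ev)
  }
  features
}

#' Simulate a hybrid strain pair from an ancestor
#'
#' Strain A is the ancestor plus optional lineage-A substitutions and
#' lineage-A elements. Strain B carries substitutions and intergenic
#' indels at the configured rates, multiplied inside second-parent mosaic
#' blocks, plus lineage-B elements placed under their rule
#' (`parent2-blocks` confines them to the mosaic blocks). Ancestral
#' elements are present in both strains. With all rates zero and only
#' ancestral elements, the strains are identical.
#'
#' @param ancestor Result of [generate_ancestor].
#' @param config A `SimulationConfig`.
#' @return List with `strain_a`, `strain_b` (`GenomeAssembly`),
#'   `features_a`, `features_b` (including TE feature rows) and `truth`.
#' @export
simulate_hybrid_strains <- function(ancestor, config) {
  if (any(config$te_plan$placement == "parent2-blocks") &&
      config$parent2_fraction <= 0) {
    stop("parent2-blocks placement requested with parent2_fraction 0")
  }
  set.seed(derive_seed(config$seed, "hybrid"))
  seqs0 <- ancestor$assembly$chromosomes
  feats0 <- ancestor$features
  # 0. second-parent mosaic blocks, drawn in ancestor coordinates so that
  # ancestral elements can be confined to shared-parent territory
  blocks0 <- list()
  for (chrom in names(seqs0)) {
    blocks0[[chrom]] <- draw_parent2_blocks(nchar(seqs0[[chrom]]),
                                            config$parent2_fraction,
                                            config$parent2_block_mean)
  }
  # 1. ancestral elements, inherited by both strains
  anc_plan <- config$te_plan[config$te_plan$label == "ancestral", ,
                             drop = FALSE]
  bmargin <- min(5000L, as.integer(config$parent2_block_mean) %/% 8L)
  anc <- plant_plan_into(seqs0, feats0, anc_plan, config$templates,
                         blocks_by_chrom = blocks0, truth_prefix = "anc",
                         block_margin = bmargin)
  # 2. strain A
  seqs_a <- anc$seqs
  feats_a <- anc$features
  truths_a <- anc$truths
  if (config$lineage_a_sub_rate > 0) {
    for (chrom in names(seqs_a)) {
      n <- nchar(seqs_a[[chrom]])
      mut <- mutate_chromosome(seqs_a[[chrom]],
                               rep(config$lineage_a_sub_rate, n),
                               0, 0, logical(n))
      seqs_a[[chrom]] <- mut$seq
    }
  }
  plan_a <- config$te_plan[config$te_plan$label == "lineage-A", ,
                           drop = FALSE]
  pa <- plant_plan_into(seqs_a, feats_a, plan_a, config$templates,
                        truth_prefix = "linA", truths = truths_a,
                        block_margin = bmargin)
  seqs_a <- pa$seqs
  feats_a <- pa$features
  truths_a <- pa$truths
  # 3. strain B: mosaic divergence then lineage-B elements
  seqs_b <- anc$seqs
  feats_b <- anc$features
  truths_b <- anc$truths
  blocks <- anc$blocks_by_chrom   # shifted by ancestral insertions
  events <- list()
  subs_b <- list()
  for (chrom in names(seqs_b)) {
    n <- nchar(seqs_b[[chrom]])
    bl <- blocks[[chrom]]
    f <- feats_b[feats_b$seqid == chrom, , drop = FALSE]
    genic <- if (nrow(f)) feature_mask(n, f$start, f$end) else logical(n)
    in_block <- if (nrow(bl)) feature_mask(n, bl$start, bl$end) else logical(n)
    mult <- ifelse(in_block, config$parent2_multiplier, 1)
    sub_rate <- ifelse(genic, config$sub_rate_genic,
                       config$sub_rate_intergenic) * mult
    # indels anywhere except near feature boundaries (so every annotation
    # coordinate remaps exactly); genic indels at a reduced rate
    near <- logical(n)
    if (nrow(f)) {
      for (i in seq_len(nrow(f))) {
        near[max(1L, f$start[i] - 60L):min(n, f$start[i] + 60L)] <- TRUE
        near[max(1L, f$end[i] - 60L):min(n, f$end[i] + 60L)] <- TRUE
      }
    }
    indel_ok <- !near
    indel_ok[seq_len(min(100L, n))] <- FALSE
    indel_ok[seq(max(1L, n - 100L), n)] <- FALSE
    indel_scale <- mult * ifelse(genic, config$genic_indel_factor, 1)
    mut <- mutate_chromosome(seqs_b[[chrom]], sub_rate,
                             config$ins_rate * indel_scale,
                             config$del_rate * indel_scale,
                             indel_ok, config$indel_mean_len,
                             config$indel_max_len)
    seqs_b[[chrom]] <- mut$seq
    events[[chrom]] <- mut$events
    subs_b[[chrom]] <- data.frame(
      pos = mut$sub_pos,
      genic = genic[mut$sub_pos + 1L],
      in_block = in_block[mut$sub_pos + 1L]
    )
    # remap block coordinates into strain-B space
    if (nrow(bl)) {
      bl$start <- remap_coords(bl$start, mut$events)
      bl$end <- remap_coords(bl$end, mut$events)
      blocks[[chrom]] <- bl
    }
  }
  feats_b <- remap_feature_df(feats_b, events)
  for (k in names(truths_b)) {
    tr <- truths_b[[k]]
    ev <- events[[tr$chrom]]
    truths_b[[k]]$start <- remap_coords(tr$start, ev)
    truths_b[[k]]$end <- remap_coords(tr$end, ev)
  }
  plan_b <- config$te_plan[config$te_plan$label == "lineage-B", ,
                           drop = FALSE]
  pb <- plant_plan_into(seqs_b, feats_b, plan_b, config$templates,
                        blocks_by_chrom = blocks, truth_prefix = "linB",
                        truths = truths_b, block_margin = bmargin)
  seqs_b <- pb$seqs
  feats_b <- pb$features
  truths_b <- pb$truths
  blocks <- pb$blocks_by_chrom
  # 4. assemble the truth table
  all_ids <- unique(c(names(truths_a), names(truths_b)))
  te <- do.call(rbind, lapply(all_ids, function(id) {
    ta <- truths_a[[id]]
    tb <- truths_b[[id]]
    ref <- if (!is.null(ta)) ta else tb
    data.frame(
      te_id = id, family = ref$family, label = ref$label,
      placement = ref$placement, chrom = ref$chrom,
      start_a = if (!is.null(ta)) ta$start else NA_integer_,
      end_a = if (!is.null(ta)) ta$end else NA_integer_,
      start_b = if (!is.null(tb)) tb$start else NA_integer_,
      end_b = if (!is.null(tb)) tb$end else NA_integer_,
      tsd_len = ref$tsd_len, tsd_offset = ref$tsd_offset,
      elem_len = ref$elem_len, stringsAsFactors = FALSE
    )
  }))
  rownames(te) <- NULL
  list(
    strain_a = genome_assembly("strainA", seqs_a),
    strain_b = genome_assembly("strainB", seqs_b),
    features_a = feats_a,
    features_b = feats_b,
    truth = list(te = te, parent2_blocks = blocks, substitutions = subs_b,
                 config_seed = config$seed)
  )
}
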