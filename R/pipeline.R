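# Orchestration: the end-to-end comparison pipeline and the command-style
# entry points (simulate / annotate / compare / digest) that write their
# outputs plus a run manifest. A thin command-line wrapper over these
# functions ships in inst/cli/teloci.R.

write_manifest <- function(out_dir, command, params, inputs = character(),
                           seed = NA) {
  man <- list(
    command = command,
    params = params,
    inputs = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else list(),
    seed = seed,
    tool_version = as.character(utils::packageVersion("teloci")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' Compare two annotated strains end to end
#'
#' Builds iLoci for both strains, resolves the flanking iLoci of every
#' strain-A TE, maps the flank iLoci onto strain B by reciprocal-best
#' alignment, classifies each TE as allelic or non-allelic, computes
#' per-TE flanking variant-density profiles, reconstructs naive sites for
#' non-allelic TEs and searches strain B for the empty site, and assembles
#' the three-hypothesis report. Mapping is restricted to the TE flank
#' iLoci unless `full_map` is set (then every iLocus is mapped and
#' genome-wide genic/intergenic density baselines are reported).
#'
#' @param genome_a,genome_b `GenomeAssembly` objects.
#' @param features_a,features_b Feature data.frames (TEs carried as
#'   features of kind `"TE"` with a `family`).
#' @param seed Seed for the permutation test.
#' @param full_map Map all iLoci instead of only TE flanks.
#' @param n_perm Permutations for the group comparison.
#' @param params Optional overrides: `min_identity`, `min_coverage`,
#'   `k_flanks`, `naive_window`, `align_params`.
#' @return List with `iloci_a`, `iloci_b`, `map` (pairs and orphans),
#'   `te_table`, `flanksets`, `profiles`, `empty_sites`, `report`,
#'   `baselines`.
#' @export
compare_strains <- function(genome_a, genome_b, features_a, features_b,
                            seed = 1L, full_map = FALSE, n_perm = 10000L,
                            params = list()) {
  p <- utils::modifyList(list(
    min_identity = 0.80, min_coverage = 0.80, k_flanks = 2L,
    naive_window = 500L, align_params = list(length_cap = 12000L)
  ), params)
  iloci_a <- build_iloci(features_a, genome_a)
  iloci_b <- build_iloci(features_b, genome_b)
  te_a <- features_a[features_a$kind == "TE", , drop = FALSE]
  te_b <- features_b[features_b$kind == "TE", , drop = FALSE]
  flanksets <- list()
  for (i in seq_len(nrow(te_a))) {
    flanksets[[te_a$id[i]]] <- flanking_iloci(
      iloci_a, te_a$seqid[i], te_a$start[i], te_a$end[i],
      k = p$k_flanks, te_id = te_a$id[i])
  }
  subset_a <- if (full_map) NULL else unique(unlist(lapply(
    flanksets, function(f) c(f$upstream, f$downstream))))
  map <- reciprocal_map(iloci_a, iloci_b, genome_a, genome_b,
                        min_identity = p$min_identity,
                        min_coverage = p$min_coverage,
                        subset_a = subset_a,
                        align_params = p$align_params)
  te_a$allelism <- NA_character_
  warns <- logical(nrow(te_a))
  for (i in seq_len(nrow(te_a))) {
    cl <- classify_te_allelism(te_a[i, ], flanksets[[te_a$id[i]]],
                               map$pairs, iloci_b, te_b)
    te_a$allelism[i] <- cl$call
    warns[i] <- cl$warn
  }
  te_a$flank_warning <- warns
  profiles <- suppressWarnings(
    flank_density_profile(te_a, flanksets, map$pairs))
  # naive-site reconstruction and empty-site search for non-allelic TEs
  empty_rows <- list()
  nonal <- te_a[te_a$allelism == "non-allelic", , drop = FALSE]
  for (i in seq_len(nrow(nonal))) {
    te <- nonal[i, ]
    up <- genome_subseq(genome_a, te$seqid, max(0L, te$start - 20L), te$start)
    down <- genome_subseq(genome_a, te$seqid, te$end,
                          min(chrom_lengths(genome_a)[[te$seqid]],
                              te$end + 20L))
    tsd <- if (nchar(up) >= 13L && nchar(down) >= 12L) {
      detect_tsd(up, down)
    } else NULL
    te_rec <- list(seqid = te$seqid, start = te$start, end = te$end,
                   tsd_len = if (is.null(tsd)) NA else tsd$length,
                   tsd_offset = if (is.null(tsd)) NA else tsd$offset)
    naive <- reconstruct_naive_site(genome_a, te_rec, window = p$naive_window)
    hit <- locate_empty_site(naive, genome_b)
    empty_rows[[length(empty_rows) + 1L]] <- data.frame(
      te_id = te$id, family = te$family, found = hit$found,
      chrom = if (hit$found) hit$chrom else NA_character_,
      position = if (hit$found) hit$position else NA_integer_
    )
  }
  empty_sites <- if (length(empty_rows)) do.call(rbind, empty_rows) else
    data.frame(te_id = character(), family = character(), found = logical(),
               chrom = character(), position = integer())
  baselines <- NULL
  if (full_map && nrow(map$pairs)) {
    amap <- stats::setNames(iloci_a$class, iloci_a$id)
    cls <- amap[map$pairs$a_id]
    baselines <- list(
      feature = c(M = mean(map$pairs$M[cls == "feature"]),
                  I = mean(map$pairs$I[cls == "feature"]),
                  D = mean(map$pairs$D[cls == "feature"])),
      intergenic = c(M = mean(map$pairs$M[cls == "intergenic"]),
                     I = mean(map$pairs$I[cls == "intergenic"]),
                     D = mean(map$pairs$D[cls == "intergenic"]))
    )
  }
  report <- hypothesis_report(profiles, empty_sites, baselines,
                              n_perm = n_perm, seed = seed)
  list(iloci_a = iloci_a, iloci_b = iloci_b, map = map, te_table = te_a,
       flanksets = flanksets, profiles = profiles,
       empty_sites = empty_sites, report = report, baselines = baselines)
}

#' Run the simulation stage
#'
#' Generates the ancestor and the two descendant strains and writes
#' FASTA + GFF3 per strain, a truth JSON, and a run manifest.
#'
#' @param config A `SimulationConfig`, or path to a YAML config file.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional seed overriding the config's seed.
#' @return The simulation result, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    config <- read_sim_config(config, seed = seed)
  } else if (!is.null(seed)) {
    # rebuild with the new seed; templates regenerate from it
    fields <- unclass(config)
    fields <- fields[setdiff(names(fields),
                             c("seed", "templates", "trna_end"))]
    config <- do.call(simulation_config, c(list(seed = seed), fields))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  anc <- generate_ancestor(config)
  sim <- simulate_hybrid_strains(anc, config)
  write_fasta(anc$assembly, file.path(out_dir, "ancestor.fa"))
  write_gff3(anc$features, file.path(out_dir, "ancestor.gff3"))
  write_fasta(sim$strain_a, file.path(out_dir, "strainA.fa"))
  write_fasta(sim$strain_b, file.path(out_dir, "strainB.fa"))
  write_gff3(sim$features_a, file.path(out_dir, "strainA.gff3"))
  write_gff3(sim$features_b, file.path(out_dir, "strainB.gff3"))
  truth <- list(
    te = sim$truth$te,
    parent2_blocks = sim$truth$parent2_blocks,
    substitution_counts = lapply(sim$truth$substitutions, function(s) {
      list(total = nrow(s), genic = sum(s$genic),
           intergenic = sum(!s$genic), in_parent2_block = sum(s$in_block))
    }),
    seed = config$seed
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  write_manifest(out_dir, "simulate",
                 params = config[c("chrom_lengths", "gc", "gene_density",
                                   "sub_rate_genic", "sub_rate_intergenic",
                                   "parent2_fraction", "parent2_multiplier")],
                 seed = config$seed)
  invisible(sim)
}

#' Run the annotation stage
#'
#' Census of TE families against reference sequences plus structural
#' anatomy of every full-length hit; writes a GFF3 of elements, a TSV
#' census and a manifest.
#'
#' @param genome_fa Genome FASTA path.
#' @param refs_fa Family reference FASTA path (headers are family names);
#'   may be `NULL`/missing for an empty census.
#' @param out_dir Output directory.
#' @return List with `census` and `hits`, invisibly.
#' @export
run_annotate <- function(genome_fa, refs_fa, out_dir) {
  if (!file.exists(genome_fa)) stop("missing input: ", genome_fa)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_fasta(genome_fa)
  refs <- if (!is.null(refs_fa) && file.exists(refs_fa)) {
    x <- Biostrings::readDNAStringSet(refs_fa)
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else character()
  cen <- census_elements(genome, refs)
  utils::write.table(cen$census, file.path(out_dir, "census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(cen$hits)) {
    anats <- vector("list", nrow(cen$hits))
    for (i in seq_len(nrow(cen$hits))) {
      h <- cen$hits[i, ]
      clen <- chrom_lengths(genome)[[h$seqid]]
      anats[[i]] <- annotate_element_anatomy(
        genome_subseq(genome, h$seqid, h$start, h$end),
        upstream_flank = genome_subseq(genome, h$seqid,
                                       max(0L, h$start - 30L), h$start),
        downstream_flank = genome_subseq(genome, h$seqid, h$end,
                                         min(clen, h$end + 30L)),
        family = h$family)
    }
    write_anatomy_gff3(anats, cen$hits, file.path(out_dir, "elements.gff3"))
  }
  write_manifest(out_dir, "annotate", params = list(),
                 inputs = c(genome_fa, if (length(refs)) refs_fa))
  invisible(cen)
}

#' Run the comparison stage
#'
#' Executes iLocus construction, reciprocal allelic mapping, flanking
#' variant densities, allelism calls, naive-site search and the hypothesis
#' report; writes TSV/JSON/BED outputs and a manifest. Chromosome ids
#' shared by the two strains are the normal allelic case; exported tracks
#' disambiguate them with a strain prefix.
#'
#' @param genome_a_fa,genome_b_fa Strain FASTA paths.
#' @param features_a_gff,features_b_gff Strain GFF3 paths (TE features of
#'   kind-mapped type carry the family in a `family` attribute).
#' @param out_dir Output directory.
#' @param seed Seed for the permutation test.
#' @param full_map Map all iLoci (slower) instead of TE flanks only.
#' @return The [compare_strains] result, invisibly.
#' @export
run_compare <- function(genome_a_fa, genome_b_fa, features_a_gff,
                        features_b_gff, out_dir, seed = 1L,
                        full_map = FALSE) {
  for (f in c(genome_a_fa, genome_b_fa, features_a_gff, features_b_gff)) {
    if (!file.exists(f)) stop("missing input: ", f)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ga <- read_fasta(genome_a_fa, name = "strainA")
  gb <- read_fasta(genome_b_fa, name = "strainB")
  fa <- read_gff3(features_a_gff, ga)
  fb <- read_gff3(features_b_gff, gb)
  res <- compare_strains(ga, gb, fa, fb, seed = seed, full_map = full_map)
  utils::write.table(res$map$pairs, file.path(out_dir, "allelic_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    res$te_table[, c("id", "family", "seqid", "start", "end", "allelism",
                     "flank_warning")],
    file.path(out_dir, "te_allelism.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$profiles, file.path(out_dir, "flank_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # per-iLocus M/I/D track (BED with the density in the score column)
  amap <- stats::setNames(seq_len(nrow(res$iloci_a)), res$iloci_a$id)
  pr <- res$map$pairs
  if (nrow(pr)) {
    loc <- res$iloci_a[amap[pr$a_id], ]
    for (metric in c("M", "I", "D")) {
      bed <- data.frame(
        chrom = paste0("strainA.", loc$seqid),
        start = loc$start, end = loc$end,
        name = pr$a_id, score = round(pr[[metric]], 4), strand = "."
      )
      utils::write.table(bed,
                         file.path(out_dir, sprintf("density_%s.bed", metric)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  rep <- res$report
  jsonlite::write_json(
    list(families = rep$families,
         pooled = list(
           n_allelic = rep$pooled$n_allelic,
           n_non_allelic = rep$pooled$n_non_allelic,
           allelic_means = as.list(rep$pooled$allelic_means),
           non_allelic_means = as.list(rep$pooled$non_allelic_means),
           p_values = lapply(rep$pooled$comparisons, function(cmp) {
             list(statistic = cmp$statistic, p_value = cmp$p_value,
                  p_ranksum = cmp$p_ranksum)
           })),
         fraction_empty_sites = rep$fraction_empty_sites,
         verdict = rep$verdict),
    file.path(out_dir, "hypothesis_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows")
  write_manifest(out_dir, "compare", params = list(full_map = full_map),
                 inputs = c(genome_a_fa, genome_b_fa, features_a_gff,
                            features_b_gff),
                 seed = seed)
  invisible(res)
}

#' Run the virtual nickase digest stage
#'
#' Digests every chromosome with the nickase motif, writes the sites as
#' BED, reports any dominant tandem period per chromosome, and writes a
#' manifest.
#'
#' @param genome_fa Genome FASTA path.
#' @param out_dir Output directory.
#' @param motif Recognition sequence.
#' @return data.frame of per-chromosome site counts and periods, invisibly.
#' @export
run_digest <- function(genome_fa, out_dir, motif = NT_BSPQI_MOTIF) {
  if (!file.exists(genome_fa)) stop("missing input: ", genome_fa)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_fasta(genome_fa)
  beds <- list()
  rows <- list()
  for (chrom in names(genome$chromosomes)) {
    sm <- virtual_nick_digest(genome$chromosomes[[chrom]], motif)
    if (nrow(sm)) {
      beds[[chrom]] <- data.frame(
        chrom = chrom, start = sm$pos, end = sm$pos + nchar(motif),
        name = sprintf("%s_nick%05d", chrom, seq_len(nrow(sm))),
        score = 0L, strand = sm$strand)
    }
    per <- detect_tandem_period(sm)
    rows[[chrom]] <- data.frame(
      seqid = chrom, n_sites = nrow(sm),
      period = if (is.null(per)) NA_real_ else per$period,
      support = if (is.null(per)) NA_integer_ else per$support)
  }
  if (length(beds)) {
    utils::write.table(do.call(rbind, beds),
                       file.path(out_dir, "nick_sites.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  periods <- do.call(rbind, rows)
  rownames(periods) <- NULL
  utils::write.table(periods, file.path(out_dir, "tandem_periods.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "digest", params = list(motif = motif),
                 inputs = genome_fa)
  invisible(periods)
}
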