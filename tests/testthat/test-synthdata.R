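# The synthetic hybrid-strain generator: placement, rates, round trips,
# truth fidelity and determinism.

test_that("the ancestor meets the requested gene count without overlaps", {
  cfg <- simulation_config(seed = 901, chrom_lengths = c(chr1 = 200000L),
                           gene_density = 0.5, gene_len_mean = 1000L,
                           gene_len_sd = 1L, tdna_density = 0)
  anc <- generate_ancestor(cfg)
  genes <- anc$features[anc$features$kind == "gene", ]
  expect_equal(nrow(genes), 100L)
  o <- genes[order(genes$start), ]
  expect_true(all(o$start[-1] >= head(o$end, -1)))
})

test_that("infeasible gene density is an error", {
  cfg <- simulation_config(seed = 902, chrom_lengths = c(chr1 = 50000L),
                           gene_density = 2, gene_len_mean = 1000L)
  expect_error(generate_ancestor(cfg), "infeasible")
})

test_that("realized GC tracks the requested GC", {
  cfg <- simulation_config(seed = 903, chrom_lengths = c(chr1 = 200000L),
                           gc = 0.49)
  anc <- generate_ancestor(cfg)
  gc <- teloci:::gc_fraction(anc$assembly$chromosomes[["chr1"]])
  expect_lt(abs(gc - 0.49), 0.01)
})

test_that("same seed gives byte-identical generator output", {
  cfg1 <- small_sim_config(904)
  cfg2 <- small_sim_config(904)
  a1 <- generate_ancestor(cfg1)
  a2 <- generate_ancestor(cfg2)
  expect_identical(a1$assembly$chromosomes, a2$assembly$chromosomes)
  expect_identical(a1$features, a2$features)
  s1 <- simulate_hybrid_strains(a1, cfg1)
  s2 <- simulate_hybrid_strains(a2, cfg2)
  expect_identical(s1$strain_a$chromosomes, s2$strain_a$chromosomes)
  expect_identical(s1$strain_b$chromosomes, s2$strain_b$chromosomes)
  expect_identical(s1$truth$te, s2$truth$te)
})

test_that("planting round-trips through every structural detector", {
  set.seed(905)
  cfg <- small_sim_config(905)
  tmpl <- cfg$templates$famA
  anc_seq <- rand_seq(20000)
  f0 <- feature_table(character(), integer(), integer())[0L, ]
  pl <- teloci:::plant_element(anc_seq, f0, 9000L, tmpl, "te1")
  s <- pl$truth$start
  e <- pl$truth$end
  el <- substr(pl$seq, s + 1L, e)
  up <- substr(pl$seq, s - 19L, s)
  down <- substr(pl$seq, e + 1L, e + 20L)
  an <- annotate_element_anatomy(el, up, down,
                                 trna_ends = c(tMi = cfg$trna_end),
                                 params = list(min_orf_aa = 300L))
  expect_equal(an$classification, "full-length")
  expect_equal(an$tir$length, 6L)
  expect_equal(an$tsd$length, tmpl$anatomy$tsd_len)
  expect_equal(an$tsd$offset, tmpl$anatomy$tsd_offset)
  expect_equal(an$ltr_pair$ltr_length, tmpl$anatomy$ltr_len)
  expect_equal(an$ltr_pair$identity, 1.0)
  expect_equal(an$pbs$match_length, tmpl$anatomy$pbs_len)
  expect_equal(an$pbs$start_offset, tmpl$anatomy$pbs_offset)
  expect_equal(an$ppt$run_length, tmpl$anatomy$ppt_len)
  expect_equal(an$ppt$end_offset, tmpl$anatomy$ppt_offset)
  expect_equal(an$orf_layout$spacer_lengths, tmpl$anatomy$spacer_len)
  expect_equal(an$orf_layout$spacer_stop_counts, tmpl$anatomy$spacer_stops)
})

test_that("a TSD offset of one is planted and detected as such", {
  set.seed(906)
  tmpl <- make_element_template("off", "solo", ltr_len = 244L,
                                tsd_len = 5L, tsd_offset = 1L)
  f0 <- feature_table(character(), integer(), integer())[0L, ]
  pl <- teloci:::plant_element(rand_seq(10000), f0, 5000L, tmpl, "te1")
  up <- substr(pl$seq, pl$truth$start - 19L, pl$truth$start)
  down <- substr(pl$seq, pl$truth$end + 1L, pl$truth$end + 20L)
  tsd <- detect_tsd(up, down)
  expect_equal(tsd$length, 5L)
  expect_equal(tsd$offset, 1L)
})

test_that("an element planted 16 bp upstream of a tDNA is start-targeted", {
  set.seed(907)
  cfg <- small_sim_config(907)
  tmpl <- cfg$templates$famC
  seq <- rand_seq(20000)
  td <- feature_table(seqid = "c1", start = 9000L, end = 9080L, strand = "+",
                      kind = "tDNA", id = "t1")
  p <- 9000L - 16L
  pl <- teloci:::plant_element(seq, td, p, tmpl, "te1")
  td_new <- pl$features[pl$features$kind == "tDNA", ]
  cls <- classify_rnap3_association(pl$truth$end, td_new)
  expect_equal(cls, "rnap3-start-targeted")
})

test_that("zero rates with only ancestral elements give identical strains", {
  cfg <- simulation_config(
    seed = 908, chrom_lengths = c(chr1 = 120000L),
    sub_rate_genic = 0, sub_rate_intergenic = 0, ins_rate = 0, del_rate = 0,
    parent2_fraction = 0.5,
    te_plan = data.frame(family = "famA", template = "full", count = 3L,
                         label = "ancestral", placement = "parent1-blocks",
                         stringsAsFactors = FALSE))
  anc <- generate_ancestor(cfg)
  sim <- simulate_hybrid_strains(anc, cfg)
  expect_identical(sim$strain_a$chromosomes, sim$strain_b$chromosomes)
  expect_identical(sim$features_a, sim$features_b)
  expect_true(all(!is.na(sim$truth$te$start_a) & !is.na(sim$truth$te$start_b)))
})

test_that("parent2-blocks placement without blocks is an error", {
  cfg <- simulation_config(
    seed = 909, chrom_lengths = c(chr1 = 100000L), parent2_fraction = 0,
    te_plan = data.frame(family = "famB", template = "solo", count = 1L,
                         label = "lineage-B", placement = "parent2-blocks",
                         stringsAsFactors = FALSE))
  anc <- generate_ancestor(cfg)
  expect_error(simulate_hybrid_strains(anc, cfg), "parent2")
})

test_that("realized substitution counts are within 3 s.e. of rate times length", {
  cfg <- simulation_config(seed = 910, chrom_lengths = c(chr1 = 500000L),
                           parent2_fraction = 0,
                           te_plan = data.frame(family = "famA",
                                                template = "solo", count = 0L,
                                                label = "ancestral",
                                                placement = "parent1-blocks",
                                                stringsAsFactors = FALSE))
  anc <- generate_ancestor(cfg)
  sim <- simulate_hybrid_strains(anc, cfg)
  subs <- sim$truth$substitutions$chr1
  genes <- anc$features[anc$features$kind != "TE", ]
  genic_len <- sum(genes$end - genes$start)
  inter_len <- 500000L - genic_len
  for (cls in c("genic", "intergenic")) {
    len <- if (cls == "genic") genic_len else inter_len
    rate <- if (cls == "genic") cfg$sub_rate_genic else cfg$sub_rate_intergenic
    got <- if (cls == "genic") sum(subs$genic) else sum(!subs$genic)
    se <- sqrt(len * rate * (1 - rate))
    expect_lt(abs(got - len * rate), 3 * se)
  }
})

test_that("planted genic/intergenic rate contrast shows up in the pipeline", {
  cfg <- simulation_config(seed = 911, chrom_lengths = c(chr1 = 250000L),
                           parent2_fraction = 0,
                           te_plan = data.frame(family = "famA",
                                                template = "full", count = 2L,
                                                label = "ancestral",
                                                placement = "parent1-blocks",
                                                stringsAsFactors = FALSE))
  anc <- generate_ancestor(cfg)
  sim <- simulate_hybrid_strains(anc, cfg)
  res <- compare_strains(sim$strain_b, sim$strain_a, sim$features_b,
                         sim$features_a, seed = 911, full_map = TRUE,
                         n_perm = 200L)
  expect_lt(res$baselines$feature[["M"]], res$baselines$intergenic[["M"]])
})

test_that("every planted element is re-detected by the census at rate zero", {
  cfg <- simulation_config(
    seed = 912, chrom_lengths = c(chr1 = 150000L),
    sub_rate_genic = 0, sub_rate_intergenic = 0, ins_rate = 0, del_rate = 0,
    te_plan = data.frame(
      family = c("famA", "famC"), template = c("full", "solo"),
      count = c(3L, 2L), label = c("ancestral", "lineage-A"),
      placement = c("parent1-blocks", "uniform-intergenic"),
      stringsAsFactors = FALSE))
  anc <- generate_ancestor(cfg)
  sim <- simulate_hybrid_strains(anc, cfg)
  refs <- c(famA = cfg$templates$famA$element_seq,
            famC = cfg$templates$famC$element_seq)
  cen <- census_elements(sim$strain_a, refs)
  truth <- sim$truth$te[!is.na(sim$truth$te$start_a), ]
  for (i in seq_len(nrow(truth))) {
    hit <- cen$hits[cen$hits$family == truth$family[i] &
                      cen$hits$start == truth$start_a[i] &
                      cen$hits$end == truth$end_a[i], ]
    expect_equal(nrow(hit), 1L, label = truth$te_id[i])
  }
  expect_equal(cen$census$full[cen$census$family == "famA"], 3L)
})

test_that("config files round-trip through YAML with seed override", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 3",
    "chrom_lengths:",
    "  chr1: 120000",
    "gene_density: 0.3",
    "te_plan:",
    "  - family: famA",
    "    template: full",
    "    count: 2",
    "    label: ancestral",
    "    placement: parent1-blocks"
  ), yml)
  cfg <- read_sim_config(yml)
  expect_equal(cfg$seed, 3L)
  expect_equal(cfg$gene_density, 0.3)
  cfg7 <- read_sim_config(yml, seed = 7L)
  expect_equal(cfg7$seed, 7L)
  writeLines(c("seed: 3", "not_a_key: 1"), yml)
  expect_error(read_sim_config(yml), "not_a_key")
})
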