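# Reciprocal-best allelic mapping and TE allelism classification.

make_annotated_genome <- function(n, n_genes, seed, name = "g") {
  set.seed(seed)
  seq <- rand_seq(n)
  slot <- n %/% n_genes
  starts <- (seq_len(n_genes) - 1L) * slot + slot %/% 4L
  f <- feature_table(seqid = "c1", start = starts, end = starts + 800L,
                     kind = "gene", id = sprintf("g%02d", seq_len(n_genes)))
  list(genome = genome_assembly(name, c(c1 = seq)), features = f)
}

test_that("identical genomes pair every iLocus with its twin, no orphans", {
  ga <- make_annotated_genome(60000L, 10L, seed = 601, name = "A")
  gb <- list(genome = genome_assembly("B", ga$genome$chromosomes),
             features = ga$features)
  ila <- build_iloci(ga$features, ga$genome)
  ilb <- build_iloci(gb$features, gb$genome)
  rm_ <- reciprocal_map(ila, ilb, ga$genome, gb$genome)
  expect_equal(nrow(rm_$pairs), nrow(ila))
  expect_equal(rm_$pairs$a_id, rm_$pairs$b_id)
  expect_equal(length(rm_$orphans_a), 0L)
  expect_equal(length(rm_$orphans_b), 0L)
  expect_true(all(rm_$pairs$identity == 1))
  expect_true(all(rm_$pairs$M == 0 & rm_$pairs$I == 0 & rm_$pairs$D == 0))
})

test_that("a duplicated locus leaves one orphan copy", {
  set.seed(602)
  # strain A carries a tandem segmental duplication of one gene locus that
  # strain B lacks: the two copies cannot both be reciprocal best
  core <- rand_seq(40000)
  dup <- substr(core, 10001, 14000)
  seq_a <- paste0(substr(core, 1, 14000), dup, substr(core, 14001, 40000))
  f_b <- feature_table(seqid = "c1",
                       start = c(2000L, 11000L, 20000L, 30000L),
                       end = c(2800L, 12800L, 20800L, 30800L),
                       kind = "gene", id = sprintf("g%d", 1:4))
  f_a <- feature_table(seqid = "c1",
                       start = c(2000L, 11000L, 15000L, 24000L, 34000L),
                       end = c(2800L, 12800L, 16800L, 24800L, 34800L),
                       kind = "gene", id = sprintf("g%d", 1:5))
  ga <- genome_assembly("A", c(c1 = seq_a))
  gb <- genome_assembly("B", c(c1 = core))
  ila <- build_iloci(f_a, ga)
  ilb <- build_iloci(f_b, gb)
  rm_ <- reciprocal_map(ila, ilb, ga, gb)
  # the duplicated gene iLoci in A (copies at 11000 and 15000) both match
  # the single B locus; only one can be reciprocal best
  dup_a <- ila$id[ila$class == "feature" &
                    ila$start %in% c(11000L, 15000L)]
  paired <- dup_a %in% rm_$pairs$a_id
  expect_equal(sum(paired), 1L)
  expect_true(any(rm_$orphans_a %in% dup_a))
})

test_that("pairing is invariant to iLocus row order", {
  ga <- make_annotated_genome(40000L, 8L, seed = 603, name = "A")
  set.seed(604)
  gb_seq <- mutate_subs(ga$genome$chromosomes[["c1"]], 100L)
  gb <- genome_assembly("B", c(c1 = gb_seq))
  ila <- build_iloci(ga$features, ga$genome)
  ilb <- build_iloci(ga$features, gb)
  rm1 <- reciprocal_map(ila, ilb, ga$genome, gb)
  perm <- sample(nrow(ila))
  rm2 <- reciprocal_map(ila[perm, ], ilb, ga$genome, gb)
  o1 <- rm1$pairs[order(rm1$pairs$a_id), ]
  o2 <- rm2$pairs[order(rm2$pairs$a_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("swapping the strains swaps roles and I/D counts exactly", {
  ga <- make_annotated_genome(40000L, 8L, seed = 605, name = "A")
  set.seed(606)
  s <- ga$genome$chromosomes[["c1"]]
  s <- mutate_subs(s, 80L)
  cut <- 21000L
  s <- paste0(substr(s, 1, cut), substr(s, cut + 7L, nchar(s)))  # 6-bp deletion
  gb <- genome_assembly("B", c(c1 = s))
  ila <- build_iloci(ga$features, ga$genome)
  ilb <- build_iloci(ga$features, gb)
  fwd <- reciprocal_map(ila, ilb, ga$genome, gb)
  rev <- reciprocal_map(ilb, ila, gb, ga$genome)
  f <- fwd$pairs[order(fwd$pairs$a_id), ]
  r <- rev$pairs[order(rev$pairs$b_id), ]
  expect_equal(f$a_id, r$b_id)
  expect_equal(f$b_id, r$a_id)
  expect_equal(f$mismatches, r$mismatches)
  expect_equal(f$inserted_bases, r$deleted_bases)
  expect_equal(f$deleted_bases, r$inserted_bases)
})

test_that("TE allelism follows presence of a same-family element between partner flanks", {
  set.seed(607)
  cfg <- small_sim_config(607)
  anc <- generate_ancestor(cfg)
  sim <- simulate_hybrid_strains(anc, cfg)
  res <- compare_strains(sim$strain_b, sim$strain_a, sim$features_b,
                         sim$features_a, seed = 607, n_perm = 200L)
  tt <- res$te_table
  truth <- sim$truth$te
  for (i in seq_len(nrow(tt))) {
    lab <- truth$label[truth$te_id == tt$id[i]]
    expected <- if (lab == "ancestral") "allelic" else "non-allelic"
    expect_equal(tt$allelism[i], expected, label = tt$id[i])
  }
})

test_that("a same-family solo LTR at the partner position counts as allelic", {
  set.seed(608)
  # focal strain has a full element; partner strain carries only a solo LTR
  # of the same family at the allelic position
  core <- rand_seq(30000)
  ltr <- rand_seq(244)
  full <- paste0(ltr, rand_seq(2000), ltr)
  pos <- 15000L
  seq_a <- paste0(substr(core, 1, pos), full, substr(core, pos + 1, 30000))
  seq_b <- paste0(substr(core, 1, pos), ltr, substr(core, pos + 1, 30000))
  gstarts <- c(3000L, 8000L, 22000L, 27000L)
  f_core <- feature_table(seqid = "c1", start = gstarts, end = gstarts + 900L,
                          kind = "gene", id = sprintf("g%d", 1:4))
  shift_feats <- function(f, at, by) {
    sel <- f$start >= at
    f$start[sel] <- f$start[sel] + by
    f$end[sel] <- f$end[sel] + by
    f
  }
  f_a <- rbind(shift_feats(f_core, pos, nchar(full)),
               feature_table(seqid = "c1", start = pos, end = pos + nchar(full),
                             kind = "TE", family = "fam1", id = "teA"))
  f_b <- rbind(shift_feats(f_core, pos, 244L),
               feature_table(seqid = "c1", start = pos, end = pos + 244L,
                             kind = "TE", family = "fam1", id = "teB"))
  ga <- genome_assembly("A", c(c1 = seq_a))
  gb <- genome_assembly("B", c(c1 = seq_b))
  res <- compare_strains(ga, gb, f_a[order(f_a$start), ],
                         f_b[order(f_b$start), ], seed = 608, n_perm = 200L)
  expect_equal(res$te_table$allelism[res$te_table$id == "teA"], "allelic")
})
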