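# iLocus partitioning and flank resolution.

test_that("a simple two-gene chromosome partitions into five iLoci", {
  set.seed(401)
  g <- genome_assembly("toy", c(chr1 = rand_seq(10000)))
  f <- feature_table(seqid = "chr1", start = c(2000L, 6000L),
                     end = c(3000L, 7000L), kind = "gene",
                     id = c("g1", "g2"))
  il <- build_iloci(f, g)
  expect_equal(nrow(il), 5L)
  expect_equal(il$start, c(0L, 2000L, 3000L, 6000L, 7000L))
  expect_equal(il$end, c(2000L, 3000L, 6000L, 7000L, 10000L))
  expect_equal(il$class, c("intergenic", "feature", "intergenic",
                           "feature", "intergenic"))
})

test_that("overlapping genes merge into one feature iLocus with two members", {
  set.seed(402)
  g <- genome_assembly("toy", c(chr1 = rand_seq(2000)))
  f <- feature_table(seqid = "chr1", start = c(100L, 400L),
                     end = c(500L, 900L), kind = "gene", id = c("g1", "g2"))
  il <- build_iloci(f, g)
  feat <- il[il$class == "feature", ]
  expect_equal(nrow(feat), 1L)
  expect_equal(feat$start, 100L)
  expect_equal(feat$end, 900L)
  expect_setequal(feat$members[[1]], c("g1", "g2"))
})

test_that("book-ended features merge and zero-length gaps are omitted", {
  set.seed(403)
  g <- genome_assembly("toy", c(chr1 = rand_seq(1000)))
  f <- feature_table(seqid = "chr1", start = c(100L, 300L),
                     end = c(300L, 500L), kind = "gene", id = c("g1", "g2"))
  il <- build_iloci(f, g)
  expect_equal(nrow(il), 3L)
  expect_equal(il$start[2], 100L)
  expect_equal(il$end[2], 500L)
})

test_that("the partition property holds on random feature sets", {
  set.seed(404)
  for (i in 1:100) {
    n <- sample(2000:20000, 1)
    g <- genome_assembly("toy", c(c1 = rand_seq(n)))
    k <- sample(0:15, 1)
    if (k > 0) {
      starts <- sort(sample(0:(n - 200L), k))
      ends <- pmin(starts + sample(50:400, k, replace = TRUE), n)
      f <- feature_table(seqid = "c1", start = starts, end = ends,
                         kind = "gene", id = sprintf("g%02d", 1:k))
    } else {
      f <- feature_table(character(), integer(), integer())[0L, ]
    }
    il <- build_iloci(f, g)
    # exact partition: lengths sum to chromosome length, intervals abut
    expect_equal(sum(il$end - il$start), n)
    expect_true(all(il$start < il$end))
    if (nrow(il) > 1L) {
      expect_equal(il$start[-1], head(il$end, -1))
    }
    expect_equal(il$start[1], 0L)
    expect_equal(il$end[nrow(il)], n)
    # every feature base is inside a feature iLocus
    if (k > 0) {
      feat <- il[il$class == "feature", ]
      expect_true(all(vapply(seq_len(k), function(j) {
        any(feat$start <= f$start[j] & feat$end >= f$end[j])
      }, logical(1))))
    }
  }
})

test_that("build_iloci is invariant to feature input order", {
  set.seed(405)
  g <- genome_assembly("toy", c(c1 = rand_seq(30000)))
  starts <- sort(sample(0:29000, 20))
  f <- feature_table(seqid = "c1", start = starts, end = starts + 500L,
                     kind = "gene", id = sprintf("g%02d", 1:20))
  il1 <- build_iloci(f, g)
  il2 <- build_iloci(f[sample(nrow(f)), ], g)
  expect_equal(il1$start, il2$start)
  expect_equal(il1$end, il2$end)
  expect_equal(il1$class, il2$class)
  expect_equal(lapply(il1$members, sort), lapply(il2$members, sort))
})

test_that("flanks of an interior TE are four distinct non-overlapping iLoci", {
  set.seed(406)
  g <- genome_assembly("toy", c(c1 = rand_seq(50000)))
  starts <- seq(5000L, 45000L, by = 5000L)
  f <- feature_table(seqid = "c1", start = starts, end = starts + 1000L,
                     kind = "gene", id = sprintf("g%d", seq_along(starts)))
  il <- build_iloci(f, g)
  # TE strictly inside the intergenic iLocus between g4 and g5
  fs <- flanking_iloci(il, "c1", 22000L, 23000L, k = 2L, te_id = "te1")
  expect_equal(length(fs$upstream), 2L)
  expect_equal(length(fs$downstream), 2L)
  expect_equal(length(unique(c(fs$upstream, fs$downstream))), 4L)
  expect_false(fs$short)
  all_ids <- c(fs$upstream, fs$downstream)
  loc <- il[match(all_ids, il$id), ]
  expect_true(all(loc$end <= 22000L | loc$start >= 23000L))
})

test_that("flanks at a chromosome end are short and flagged", {
  set.seed(407)
  g <- genome_assembly("toy", c(c1 = rand_seq(20000)))
  f <- feature_table(seqid = "c1", start = c(0L, 5000L), end = c(1000L, 6000L),
                     kind = c("TE", "gene"), id = c("te1", "g1"))
  il <- build_iloci(f, g)
  fs <- flanking_iloci(il, "c1", 0L, 1000L, k = 2L, te_id = "te1")
  expect_equal(length(fs$upstream), 0L)
  expect_equal(length(fs$downstream), 2L)
  expect_true(fs$short)
})

test_that("flank resolution equals a brute-force nearest-interval search", {
  set.seed(408)
  for (i in 1:50) {
    n <- 30000L
    g <- genome_assembly("toy", c(c1 = rand_seq(n)))
    starts <- sort(sample(seq(1000L, 28000L, by = 1500L),
                          sample(4:10, 1)))
    f <- feature_table(seqid = "c1", start = starts, end = starts + 700L,
                       kind = "gene", id = sprintf("g%d", seq_along(starts)))
    il <- build_iloci(f, g)
    ts <- sample(0:(n - 600L), 1)
    te <- c(ts, ts + 500L)
    fs <- flanking_iloci(il, "c1", te[1], te[2], k = 2L)
    up_o <- il[il$end <= te[1], ]
    up_o <- up_o[order(up_o$end, decreasing = TRUE), ]
    down_o <- il[il$start >= te[2], ]
    down_o <- down_o[order(down_o$start), ]
    expect_equal(fs$upstream, head(up_o$id, 2))
    expect_equal(fs$downstream, head(down_o$id, 2))
  }
})

test_that("a TE interval outside the genome is an error", {
  set.seed(409)
  g <- genome_assembly("toy", c(c1 = rand_seq(1000)))
  il <- build_iloci(feature_table(character(), integer(), integer())[0L, ], g)
  expect_error(flanking_iloci(il, "c1", 900L, 1200L), "outside")
  expect_error(flanking_iloci(il, "cZ", 10L, 20L), "unknown")
})
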