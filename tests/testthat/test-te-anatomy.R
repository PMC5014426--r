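# Structural detectors: worked examples with the published anatomy values
# and brute-force oracle equivalence on random inputs.

guard_tir_six <- function(internal, left = "TGTAAG", right = "CTTACA") {
  # force the base after the left hexamer to break a 7-bp inverted repeat
  el <- paste0(left, internal, right)
  n <- nchar(el)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  partner <- substr(el, n - 6L, n - 6L)
  if (substr(el, 7L, 7L) == comp[[partner]]) {
    substr(el, 7L, 7L) <- setdiff(c("A", "C", "G", "T"), comp[[partner]])[1L]
  }
  el
}

test_that("the TG...CA terminal inverted repeat of the published element is 6 bp", {
  set.seed(201)
  el <- guard_tir_six(rand_seq(300))
  tir <- find_terminal_inverted_repeat(el, max_mismatch = 0L)
  expect_equal(tir$length, 6L)
  expect_equal(tir$left_seq, "TGTAAG")
  expect_equal(tir$right_seq, "CTTACA")
  expect_equal(tir$mismatches, 0L)
  expect_true(tir$conforming)
})

test_that("the minimal TG...CA repeat is detected", {
  set.seed(202)
  # interior chosen so nothing extends the 3-bp repeat
  el <- "TGACCCCCCCCCCCCCCCTCA"
  tir <- find_terminal_inverted_repeat(el)
  expect_equal(tir$length, 3L)
  expect_equal(tir$left_seq, "TGA")
  expect_true(tir$conforming)
})

test_that("TIR detector equals the exhaustive oracle on random sequences", {
  set.seed(203)
  for (i in 1:200) {
    s <- rand_seq(sample(20:400, 1))
    got <- find_terminal_inverted_repeat(s, max_mismatch = 0L)
    exp <- oracle_tir(s, 0L)
    if (is.null(exp)) expect_null(got) else expect_equal(got$length, exp)
  }
})

test_that("the published offset-by-one target-site duplication is found", {
  set.seed(204)
  up <- paste0(rand_seq(40), "G", "ATTTTT")
  down <- paste0("ATTTT", "C", rand_seq(40))
  tsd <- detect_tsd(up, down, min_len = 4L, max_len = 12L, offset_tol = 1L,
                    max_mismatch = 0L)
  expect_equal(tsd$length, 5L)
  expect_equal(tsd$offset, 1L)
  expect_equal(tsd$upstream_copy, "ATTTT")
  expect_equal(tsd$downstream_copy, "ATTTT")
})

test_that("an identical flanking 9-mer gives a 9-bp zero-offset TSD", {
  set.seed(205)
  up <- paste0("C", rand_seq(20), "C", "GATTACAAG")
  down <- paste0("GATTACAAG", "T", rand_seq(20))
  tsd <- detect_tsd(up, down)
  expect_equal(tsd$length, 9L)
  expect_equal(tsd$offset, 0L)
})

test_that("TSD detector matches the oracle and is usually silent on random flanks", {
  set.seed(206)
  hits <- 0L
  for (i in 1:1000) {
    up <- rand_seq(20)
    down <- rand_seq(20)
    got <- detect_tsd(up, down, min_len = 4L)
    exp <- oracle_tsd(up, down, min_len = 4L)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      hits <- hits + 1L
      expect_equal(got$length, exp$length)
      expect_equal(got$offset, exp$offset)
    }
  }
  expect_lte(hits, 50L)   # none in >= 95% of draws
})

test_that("an exact planted LTR pair of 244 bp is recovered at identity 1", {
  set.seed(207)
  L <- rand_seq(244)
  substr(L, 1, 1) <- "T"   # avoid pathological homopolymer ends
  el <- paste0(L, rand_seq(2500), L)
  lp <- find_ltr_pair(el)
  expect_equal(lp$ltr_length, 244L)
  expect_equal(lp$identity, 1.0)
  expect_equal(lp$ltr5, c(0L, 244L))
  expect_equal(lp$ltr3, c(nchar(el) - 244L, nchar(el)))
})

test_that("an element without repeated termini has no LTR pair", {
  set.seed(208)
  expect_null(find_ltr_pair(rand_seq(3000)))
})

test_that("a 3%-substituted LTR pair is recovered within tolerance", {
  set.seed(209)
  for (i in 1:10) {
    L <- rand_seq(244)
    L2 <- mutate_subs(L, 7L)   # 7/244 ~ 3%
    el <- paste0(L, rand_seq(2500), L2)
    lp <- find_ltr_pair(el)
    expect_false(is.null(lp))
    expect_lte(abs(lp$ltr_length - 244L), 2L)
    expect_lte(abs(lp$identity - (1 - 7 / 244)), 0.011)
  }
})

test_that("the PBS is the reverse complement of the tRNA 3' terminus", {
  set.seed(210)
  trna <- paste0(rand_seq(17), "CCA")
  pbs14 <- rc_chars(substr(trna, 7, 20))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  guard <- setdiff(c("A", "C", "G", "T"), comp[[substr(trna, 6, 6)]])[1]
  internal <- paste0(rand_seq(2), pbs14, guard, rand_seq(60))
  hit <- find_pbs(internal, c(tMi = trna), min_match = 10L)
  expect_equal(hit$match_length, 14L)
  expect_equal(hit$start_offset, 2L)
  expect_equal(hit$trna_id, "tMi")
  # no tRNA provided
  expect_null(find_pbs(internal, character()))
})

test_that("PBS detector equals the oracle and is rarely fooled by chance", {
  set.seed(211)
  trnas <- setNames(replicate(10, rand_seq(20)), paste0("t", 1:10))
  hits <- 0L
  for (i in 1:500) {
    internal <- rand_seq(80)
    got <- find_pbs(internal, trnas, min_match = 10L)
    exp <- oracle_pbs(internal, trnas, min_match = 10L)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      hits <- hits + 1L
      expect_equal(got[c("start_offset", "match_length")],
                   exp[c("start_offset", "match_length")])
    }
  }
  expect_lte(hits, 5L)   # none in >= 99% of draws
})

test_that("a 13-purine tract abutting the LTR is reported exactly", {
  set.seed(212)
  run13 <- "AGGAGAAAGGGAG"
  tail <- paste0(rand_seq(60), "C", run13)
  ppt <- find_ppt(tail, min_run = 8L, search_window = 5L)
  expect_equal(ppt$run_length, 13L)
  expect_equal(ppt$end_offset, 0L)
  expect_equal(ppt$seq, run13)
  # all-pyrimidine tail
  expect_null(find_ppt(paste(sample(c("C", "T"), 50, TRUE), collapse = "")))
})

test_that("PPT detector equals the brute-force longest-run oracle", {
  set.seed(213)
  for (i in 1:200) {
    tail <- rand_seq(sample(30:120, 1), gc = runif(1, 0.3, 0.7))
    got <- find_ppt(tail, min_run = 5L, search_window = 8L)
    exp <- oracle_ppt(tail, min_run = 5L, window = 8L)
    if (is.null(exp)) {
      expect_null(got)
    } else {
      expect_equal(got$run_length, exp$run_length)
    }
  }
})

test_that("a stop-free 900-bp frame yields one 300-aa ORF", {
  set.seed(214)
  nonstop <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                       c("A","C","G","T")), 1, paste0,
                           collapse = ""), c("TAA", "TAG", "TGA"))
  seq <- paste(sample(nonstop, 300, replace = TRUE), collapse = "")
  lay <- annotate_orf_layout(seq, min_orf_aa = 250L)
  frames0 <- lay$orfs[lay$orfs$frame == 0L, ]
  expect_equal(nrow(frames0), 1L)
  expect_equal(frames0$length_aa, 300L)
  expect_equal(frames0$start, 0L)
  expect_equal(frames0$end, 900L)
})

test_that("ORF layout equals the brute-force frame enumeration", {
  set.seed(215)
  for (i in 1:100) {
    s <- rand_seq(sample(300:900, 1))
    got <- annotate_orf_layout(s, min_orf_aa = 20L)$orfs
    exp <- oracle_orfs(s, 20L)
    if (is.null(exp)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, unname(exp[, "start"]))
      expect_equal(got$end, unname(exp[, "end"]))
      expect_equal(got$length_aa, unname(exp[, "aa"]))
    }
  }
})

test_that("RNAP3 association follows the published insertion geometry", {
  td <- feature_table(seqid = "c", start = 5000L, end = 5080L, strand = "+",
                      kind = "tDNA", id = "t1")
  # boundary 16 bp upstream of the mature start
  expect_equal(classify_rnap3_association(5000L - 16L, td),
               "rnap3-start-targeted")
  # boundary 5 bp inside the upstream end of the tDNA
  expect_equal(classify_rnap3_association(5005L, td), "rnap3-internal")
  # boundary 40 bp away: adjacent
  expect_equal(classify_rnap3_association(5120L, td), "rnap3-adjacent")
  # 10 kb away: unassociated
  expect_equal(classify_rnap3_association(15000L, td), "unassociated")
  # minus-strand gene: upstream is to the right
  td_m <- feature_table(seqid = "c", start = 5000L, end = 5080L, strand = "-",
                        kind = "tDNA", id = "t2")
  expect_equal(classify_rnap3_association(5080L + 16L, td_m),
               "rnap3-start-targeted")
})

test_that("RNAP3 association is strand-symmetric under mirroring", {
  set.seed(216)
  L <- 20000L
  for (i in 1:50) {
    s <- sample(1000:18000, 1)
    st <- sample(c("+", "-"), 1)
    td <- feature_table(seqid = "c", start = s, end = s + 80L, strand = st,
                        kind = "tDNA", id = "t1")
    b <- sample(0:L, 1)
    mirr <- feature_table(seqid = "c", start = L - (s + 80L), end = L - s,
                          strand = if (st == "+") "-" else "+",
                          kind = "tDNA", id = "t1")
    expect_equal(classify_rnap3_association(b, td),
                 classify_rnap3_association(L - b, mirr))
  }
})

test_that("dimeric RNAP3 genes obey the 5-26 nt gap band", {
  mk <- function(gaps, strand = "+") {
    starts <- cumsum(c(1000L, 80L + gaps))
    feature_table(seqid = "c", start = starts, end = starts + 80L,
                  strand = strand, kind = "tDNA",
                  id = sprintf("t%d", seq_along(starts)))
  }
  p12 <- detect_dimeric_rnap3(mk(c(12L, 400L)))
  expect_equal(nrow(p12), 1L)
  expect_equal(p12$gap, 12L)
  expect_equal(p12$upstream_id, "t1")
  expect_equal(nrow(detect_dimeric_rnap3(mk(c(4L, 400L)))), 0L)
  expect_equal(nrow(detect_dimeric_rnap3(mk(c(27L, 400L)))), 0L)
  # boundary values included
  expect_equal(nrow(detect_dimeric_rnap3(mk(c(5L, 26L)))), 2L)
  # minus strand: transcription order reversed
  m <- detect_dimeric_rnap3(mk(c(12L, 400L), strand = "-"))
  expect_equal(m$upstream_id, "t2")
})

test_that("dimeric detection equals a brute-force adjacent scan", {
  set.seed(217)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    starts <- sort(sample(seq(0L, 5000L, by = 100L), n)) +
      sample(0:50, n, replace = TRUE)
    f <- feature_table(seqid = "c", start = starts, end = starts + 80L,
                       strand = sample(c("+", "-"), n, replace = TRUE),
                       kind = "tDNA", id = sprintf("t%d", 1:n))
    got <- detect_dimeric_rnap3(f)
    # oracle: explicit adjacent-pair scan
    fo <- f[order(f$start), ]
    exp_n <- 0L
    for (k in seq_len(nrow(fo) - 1L)) {
      gap <- fo$start[k + 1L] - fo$end[k]
      if (fo$strand[k] == fo$strand[k + 1L] && gap >= 5L && gap <= 26L) {
        exp_n <- exp_n + 1L
      }
    }
    expect_equal(nrow(got), exp_n)
  }
})
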