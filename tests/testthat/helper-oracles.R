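# Independent brute-force oracles and small fixture builders. These are
# deliberately naive re-implementations (loops over every candidate) kept
# separate from the package's own code paths.

rc_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# longest terminal inverted repeat: try every length explicitly
oracle_tir <- function(seq, max_mm = 0L, min_len = 2L) {
  n <- nchar(seq)
  best <- NULL
  for (L in min_len:(n %/% 2L)) {
    left <- substr(seq, 1L, L)
    right_rc <- rc_chars(substr(seq, n - L + 1L, n))
    lv <- strsplit(left, "")[[1]]
    rv <- strsplit(right_rc, "")[[1]]
    mm <- sum(lv != rv | lv == "N" | rv == "N")
    if (mm <= max_mm) best <- L
  }
  best
}

# TSD: try every (length, offset) pair
oracle_tsd <- function(up, down, min_len = 4L, max_len = 12L,
                       offset_tol = 1L, max_mm = 0L) {
  nu <- nchar(up)
  best <- NULL
  for (L in max_len:min_len) {
    for (o in 0L:offset_tol) {
      a <- strsplit(substr(up, nu - L - o + 1L, nu - o), "")[[1]]
      b <- strsplit(substr(down, 1L, L), "")[[1]]
      mm <- sum(a != b | a == "N" | b == "N")
      if (mm <= max_mm &&
          (is.null(best) || L > best$length ||
           (L == best$length && o < best$offset))) {
        best <- list(length = L, offset = o)
      }
    }
    if (!is.null(best)) break   # lengths tried in decreasing order
  }
  best
}

# PPT: every substring tested for purity and end offset
oracle_ppt <- function(tail, min_run = 8L, window = 5L) {
  n <- nchar(tail)
  best <- NULL
  for (s in 1:n) {
    for (e in s:n) {
      if (n - e > window) next
      w <- substr(tail, s, e)
      if (grepl("[^AG]", w)) next
      len <- e - s + 1L
      if (len >= min_run && (is.null(best) || len > best$run_length)) {
        # must be maximal run (not extendable leftwards) to match the
        # longest-run semantics
        if (s == 1L || !substr(tail, s - 1L, s - 1L) %in% c("A", "G")) {
          best <- list(run_length = len, end_offset = n - e)
        }
      }
    }
  }
  best
}

# PBS: every (start, tRNA, match length) combination
oracle_pbs <- function(internal, trna_ends, min_match = 10L, window = 30L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  iv <- strsplit(internal, "")[[1]]
  best <- NULL
  for (id in names(trna_ends)) {
    tv <- strsplit(trna_ends[[id]], "")[[1]]
    m <- length(tv)
    for (s in 0:min(window, length(iv) - min_match)) {
      k <- 0L
      while (k < m && s + k < length(iv) &&
             iv[s + k + 1L] == comp[[tv[m - k]]]) k <- k + 1L
      if (k >= min_match && (is.null(best) || k > best$match_length ||
                             (k == best$match_length && s < best$start_offset))) {
        best <- list(start_offset = s, match_length = k, trna_id = id)
      }
    }
  }
  best
}

# forward-frame ORFs: explicit codon walk per frame
oracle_orfs <- function(seq, min_aa) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    run_start <- NULL
    naa <- 0L
    for (ci in seq_len(ncod)) {
      cod <- substr(seq, f + 3L * ci - 2L, f + 3L * ci)
      if (cod %in% stops) {
        if (!is.null(run_start) && naa >= min_aa) {
          out[[length(out) + 1L]] <- c(start = f + 3L * (run_start - 1L),
                                       end = f + 3L * ci, aa = naa)
        }
        run_start <- NULL
        naa <- 0L
      } else {
        if (is.null(run_start)) run_start <- ci
        naa <- naa + 1L
      }
    }
    if (!is.null(run_start) && naa >= min_aa) {
      out[[length(out) + 1L]] <- c(start = f + 3L * (run_start - 1L),
                                   end = f + 3L * ncod, aa = naa)
    }
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  m[order(m[, "start"]), , drop = FALSE]
}

# both-strand motif scan by direct substring comparison
oracle_nick <- function(seq, motif) {
  n <- nchar(seq)
  m <- nchar(motif)
  if (n < m) return(data.frame(pos = integer(), strand = character()))
  words <- substring(seq, 1:(n - m + 1L), m:n)
  fwd <- which(words == motif) - 1L
  rev <- which(words == rc_chars(motif)) - 1L
  df <- data.frame(pos = c(fwd, rev),
                   strand = c(rep("+", length(fwd)), rep("-", length(rev))))
  df <- df[order(df$pos, df$strand), ]
  rownames(df) <- NULL
  df
}

# global affine-gap alignment score (Gotoh), quadratic DP
oracle_align_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 6, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (insertion in a)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1L)) X[i, 1] <- -gap_open - gap_extend * (i - 1L)
  for (j in 2:(m + 1L)) Y[1, j] <- -gap_open - gap_extend * (j - 1L)
  for (i in 1:(n + 1L)) {
    for (j in 1:(m + 1L)) {
      if (i > 1L && j > 1L) {
        s <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
        M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                       Y[i - 1L, j - 1L]) + s
      }
      if (i > 1L) {
        X[i, j] <- max(X[i - 1L, j] - gap_extend,
                       M[i - 1L, j] - gap_open - gap_extend,
                       Y[i - 1L, j] - gap_open - gap_extend)
      }
      if (j > 1L) {
        Y[i, j] <- max(Y[i, j - 1L] - gap_extend,
                       M[i, j - 1L] - gap_open - gap_extend,
                       X[i, j - 1L] - gap_open - gap_extend)
      }
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# apply k substitutions at distinct random positions
mutate_subs <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  idx <- sample(length(v), k)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

# a small simulation config used across tests (fast, ~150 kb)
small_sim_config <- function(seed, ...) {
  simulation_config(
    seed = seed,
    chrom_lengths = c(chr1 = 150000L),
    parent2_block_mean = 20000L,
    te_plan = data.frame(
      family = c("famA", "famB", "famC"),
      template = c("full", "full", "solo"),
      count = c(2L, 2L, 1L),
      label = c("ancestral", "lineage-B", "lineage-A"),
      placement = c("parent1-blocks", "parent2-blocks",
                    "uniform-intergenic"),
      stringsAsFactors = FALSE
    ),
    ...
  )
}
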