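# Element planting with target-site duplication, and insertion-site
# selection under the placement rules.

# Insert an element at 0-based position p of seq, duplicating tsd_len
# target bases on both sides; with offset o the upstream copy carries o
# extra duplicated bases (the last o bases of the target site) between it
# and the element. Returns the new sequence and the element interval.
insert_element_at <- function(seq, p, element_seq, tsd_len, offset) {
  n <- nchar(seq)
  stopifnot(p >= tsd_len, p + tsd_len <= n)
  t <- s_sub(seq, p, p + tsd_len)
  u <- if (offset > 0L) s_sub(t, tsd_len - offset, tsd_len) else ""
  newseq <- paste0(s_sub(seq, 0L, p + tsd_len), u, element_seq,
                   s_sub(seq, p, n))
  s <- p + tsd_len + offset
  list(seq = newseq, start = s, end = s + nchar(element_seq),
       ins_len = tsd_len + offset + nchar(element_seq))
}

# check that the planted TSD (and TIR for full elements) is recoverable
# exactly as recorded; ambient sequence can otherwise extend the repeat
planted_ok <- function(seq, s, e, tsd_len, offset) {
  if (tsd_len == 0L) return(TRUE)
  up <- s_sub(seq, max(0L, s - 20L), s)
  down <- s_sub(seq, e, min(nchar(seq), e + 20L))
  if (nchar(up) < 13L || nchar(down) < 12L) return(FALSE)
  td <- detect_tsd(up, down, min_len = 4L, max_len = 12L, offset_tol = 1L,
                   max_mismatch = 0L)
  !is.null(td) && td$length == tsd_len && td$offset == offset
}

# plant one element into a chromosome sequence, shifting features; the
# target-site neighbourhood is edited minimally (two guard bases) when the
# ambient sequence would make the planted TSD ambiguous
plant_element <- function(seq, features_chrom, p, template, te_id,
                          family = template$family) {
  an <- template$anatomy
  L <- an$tsd_len
  o <- an$tsd_offset
  if (p < 1000L || p + L + 1000L > nchar(seq)) stop("position out of range")
  if (nrow(features_chrom) &&
      any(features_chrom$start < p & features_chrom$end > p)) {
    stop("insertion position inside a feature")
  }
  base4 <- c("A", "C", "G", "T")
  done <- FALSE
  for (b1 in c("", base4)) {
    for (b2 in c("", base4)) {
      trial <- seq
      if (b1 != "") substr(trial, p, p) <- b1            # base before target
      if (b2 != "") substr(trial, p + L + 1L, p + L + 1L) <- b2  # base after
      ins <- insert_element_at(trial, p, template$element_seq, L, o)
      if (planted_ok(ins$seq, ins$start, ins$end, L, o)) {
        done <- TRUE
        break
      }
    }
    if (done) break
  }
  if (!done) stop("could not plant an unambiguous TSD at position ", p)
  f <- features_chrom
  if (nrow(f)) {
    shift <- f$start >= p
    f$start[shift] <- f$start[shift] + ins$ins_len
    f$end[shift] <- f$end[shift] + ins$ins_len
  }
  te_row <- data.frame(
    seqid = if (nrow(f)) f$seqid[1L] else NA_character_,
    start = ins$start, end = ins$end, strand = "+", kind = "TE",
    family = family, id = te_id, type = "mobile_genetic_element",
    stringsAsFactors = FALSE
  )
  list(seq = ins$seq, features = f, te = te_row,
       truth = list(start = ins$start, end = ins$end, tsd_len = L,
                    tsd_offset = o, elem_len = nchar(template$element_seq)))
}

intersect_intervals <- function(a, b) {
  pieces <- list()
  for (i in seq_len(nrow(b))) {
    s <- pmax(a$start, b$start[i])
    e <- pmin(a$end, b$end[i])
    keep <- e - s > 0L
    if (any(keep)) pieces[[length(pieces) + 1L]] <-
        data.frame(start = s[keep], end = e[keep])
  }
  if (!length(pieces)) return(data.frame(start = integer(), end = integer()))
  do.call(rbind, pieces)
}

complement_intervals <- function(b, n) {
  if (is.null(b) || !nrow(b)) return(data.frame(start = 0L, end = n))
  b <- b[order(b$start), , drop = FALSE]
  data.frame(start = c(0L, b$end), end = c(b$start, n))
}

# candidate intergenic gaps of a chromosome, as a data.frame
intergenic_gaps <- function(n, features_chrom, margin = 200L) {
  if (!nrow(features_chrom)) {
    return(data.frame(start = margin, end = n - margin))
  }
  f <- features_chrom[order(features_chrom$start), , drop = FALSE]
  starts <- c(0L, f$end)
  ends <- c(f$start, n)
  g <- data.frame(start = starts + margin, end = ends - margin)
  g[g$end - g$start > 0L, , drop = FALSE]
}

# shrink intervals by m on both sides, dropping those that vanish
shrink_intervals <- function(b, m) {
  out <- data.frame(start = b$start + m, end = b$end - m)
  out[out$end - out$start > 0L, , drop = FALSE]
}

# choose an insertion position under a placement rule; returns a 0-based
# position or NA when no site is available. Block rules keep the insertion
# at least block_margin inside the block so that the element's flanking
# region shares the block's parental origin (the element is "embedded" in
# block sequence, flanks included).
choose_site <- function(n, features_chrom, rule, blocks = NULL,
                        margin = 1500L, block_margin = 5000L) {
  if (rule == "rnap3-targeted") {
    td <- features_chrom[features_chrom$kind == "tDNA" &
                           features_chrom$strand == "+", , drop = FALSE]
    td <- td[td$start > margin + 40L, , drop = FALSE]
    if (!nrow(td)) return(NA_integer_)
    g <- td[sample.int(nrow(td), 1L), ]
    return(g$start - 16L)
  }
  gaps <- intergenic_gaps(n, features_chrom)
  gaps <- gaps[gaps$start > margin & gaps$end < n - margin, , drop = FALSE]
  if (rule == "parent2-blocks") {
    if (is.null(blocks) || !nrow(blocks)) {
      stop("parent2-blocks placement requested but no parent2 blocks exist")
    }
    gaps <- intersect_intervals(gaps, shrink_intervals(blocks, block_margin))
    if (!nrow(gaps)) return(NA_integer_)
  } else if (rule == "parent1-blocks") {
    # territory shared with the focal parent: the complement of the blocks
    comp <- complement_intervals(blocks, n)
    gaps <- intersect_intervals(gaps, shrink_intervals(comp, block_margin))
    if (!nrow(gaps)) return(NA_integer_)
  }
  if (!nrow(gaps)) return(NA_integer_)
  w <- gaps$end - gaps$start
  i <- sample.int(nrow(gaps), 1L, prob = w)
  gaps$start[i] + sample.int(w[i], 1L) - 1L
}
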