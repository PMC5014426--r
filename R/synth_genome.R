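# Ancestor genome generation and the mutation engine.

#' Generate an ancestor genome with gene and tDNA annotation
#'
#' Random sequence at the configured GC content; genes are placed
#' slot-wise (one gene per equal slot, jittered within the slot) so the
#' requested density is met without overlaps, and tDNAs are dropped into
#' inter-gene gaps. Reproducible per config seed.
#'
#' @param config A `SimulationConfig`.
#' @return List with `assembly` (`GenomeAssembly`) and `features`.
#' @export
generate_ancestor <- function(config) {
  set.seed(derive_seed(config$seed, "ancestor"))
  chroms <- character()
  feats <- list()
  for (chrom in names(config$chrom_lengths)) {
    n <- config$chrom_lengths[[chrom]]
    seq <- random_dna(n, config$gc)
    n_genes <- round(n / 1000 * config$gene_density)
    rows <- NULL
    if (n_genes > 0L) {
      slot <- n %/% n_genes
      if (slot < config$gene_len_min + 120L ||
          config$gene_len_mean > slot - 80L) {
        stop("gene density infeasible for chromosome length ", n)
      }
      glen <- pmax(config$gene_len_min,
                   pmin(round(stats::rnorm(n_genes, config$gene_len_mean,
                                           config$gene_len_sd)),
                        slot - 80L))
      gstart <- (seq_len(n_genes) - 1L) * slot + 30L +
        vapply(slot - glen - 60L, function(m) sample.int(m, 1L), integer(1L))
      rows <- data.frame(
        seqid = chrom, start = as.integer(gstart),
        end = as.integer(gstart + glen),
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        kind = "gene", family = NA_character_,
        id = sprintf("%s_g%04d", chrom, seq_len(n_genes)), type = "gene",
        stringsAsFactors = FALSE
      )
    }
    n_td <- round(n / 1000 * config$tdna_density)
    if (n_td > 0L && !is.null(rows) && nrow(rows) > 1L) {
      gaps <- data.frame(start = utils::head(rows$end, -1L),
                         end = rows$start[-1L])
      gaps <- gaps[gaps$end - gaps$start >= config$tdna_len + 120L, ,
                   drop = FALSE]
      pick <- sample(seq_len(nrow(gaps)), min(n_td, nrow(gaps)))
      tstart <- vapply(pick, function(i) {
        as.integer(gaps$start[i] + 60L +
                     sample.int(gaps$end[i] - gaps$start[i] -
                                  config$tdna_len - 120L + 1L, 1L) - 1L)
      }, integer(1L))
      rows <- rbind(rows, data.frame(
        seqid = chrom, start = tstart, end = tstart + config$tdna_len,
        strand = sample(c("+", "-"), length(pick), replace = TRUE,
                        prob = c(0.7, 0.3)),
        kind = "tDNA", family = NA_character_,
        id = sprintf("%s_t%04d", chrom, seq_along(pick)), type = "tRNA",
        stringsAsFactors = FALSE
      ))
    }
    chroms[[chrom]] <- seq
    if (!is.null(rows)) feats[[chrom]] <- rows[order(rows$start), , drop = FALSE]
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    feature_table(character(), integer(), integer())[0L, ]
  rownames(features) <- NULL
  list(assembly = genome_assembly("ancestor", chroms), features = features)
}

# per-base logical mask covering feature intervals
feature_mask <- function(n, starts, ends) {
  m <- logical(n)
  for (i in seq_along(starts)) m[(starts[i] + 1L):ends[i]] <- TRUE
  m
}

# Mutate one chromosome. sub_rate is a per-base vector; indel event rates
# are per-base vectors as well, but events are only drawn where
# indel_ok is TRUE (kept away from feature boundaries so coordinates remap
# exactly). Returns the new sequence, the indel event lists and the
# 0-based substitution positions.
mutate_chromosome <- function(seq, sub_rate, ins_rate, del_rate, indel_ok,
                              mean_len = 2L, max_len = 50L) {
  n <- nchar(seq)
  chars <- s_chars(seq)
  sub_idx <- which(stats::runif(n) < sub_rate)
  if (length(sub_idx)) {
    base4 <- c("A", "C", "G", "T")
    cur <- match(chars[sub_idx], base4)
    off <- sample.int(3L, length(sub_idx), replace = TRUE)
    ok <- !is.na(cur)   # leave N untouched
    chars[sub_idx[ok]] <- base4[((cur[ok] - 1L + off[ok]) %% 4L) + 1L]
    sub_idx <- sub_idx[ok]
  }
  del_pos <- which(stats::runif(n) < del_rate & indel_ok)
  del_len <- pmin(stats::rgeom(length(del_pos), 1 / mean_len) + 1L, max_len)
  # keep deletions fully inside allowed territory and non-overlapping
  keep <- logical(length(del_pos))
  last_end <- -1L
  for (i in seq_along(del_pos)) {
    e <- del_pos[i] + del_len[i]
    if (del_pos[i] > last_end && e <= n && all(indel_ok[del_pos[i]:e])) {
      keep[i] <- TRUE
      last_end <- e + 1L
    }
  }
  del_pos <- del_pos[keep] - 1L   # to 0-based
  del_len <- del_len[keep]
  ins_pos <- which(stats::runif(n) < ins_rate & indel_ok) - 1L
  ins_pos <- setdiff(ins_pos, unlist(mapply(function(p, l) p:(p + l),
                                            del_pos, del_len,
                                            SIMPLIFY = FALSE)))
  ins_len <- pmin(stats::rgeom(length(ins_pos), 1 / mean_len) + 1L, max_len)
  ins_seq <- vapply(ins_len, random_dna, character(1L))
  # assemble: walk events in order
  ev <- rbind(
    if (length(del_pos)) data.frame(pos = del_pos, len = del_len,
                                    type = "D", seq = "") else NULL,
    if (length(ins_pos)) data.frame(pos = ins_pos, len = ins_len,
                                    type = "I", seq = ins_seq) else NULL
  )
  if (!is.null(ev) && nrow(ev)) {
    ev <- ev[order(ev$pos), , drop = FALSE]
    pieces <- character()
    cursor <- 0L
    base <- paste(chars, collapse = "")
    for (i in seq_len(nrow(ev))) {
      pieces <- c(pieces, s_sub(base, cursor, ev$pos[i]))
      if (ev$type[i] == "I") {
        pieces <- c(pieces, ev$seq[i])
        cursor <- ev$pos[i]
      } else {
        cursor <- ev$pos[i] + ev$len[i]
      }
    }
    pieces <- c(pieces, s_sub(base, cursor, n))
    newseq <- paste(pieces, collapse = "")
  } else {
    newseq <- paste(chars, collapse = "")
    ev <- data.frame(pos = integer(), len = integer(), type = character(),
                     seq = character())
  }
  list(seq = newseq, events = ev, sub_pos = sub_idx - 1L)
}

# remap 0-based ancestor coordinates through an event list
remap_coords <- function(x, events) {
  if (!nrow(events)) return(x)
  del <- events[events$type == "D", , drop = FALSE]
  ins <- events[events$type == "I", , drop = FALSE]
  x2 <- x
  if (nrow(del)) {
    j <- findInterval(x, del$pos)
    inside <- j >= 1L & x < del$pos[pmax(j, 1L)] + del$len[pmax(j, 1L)]
    x2[inside] <- del$pos[j[inside]]
    cumdel <- cumsum(del$len)
    k <- findInterval(x2, del$pos + del$len)
    x2 <- x2 - ifelse(k >= 1L, cumdel[pmax(k, 1L)], 0L)
  }
  if (nrow(ins)) {
    cumins <- cumsum(ins$len)
    k <- findInterval(if (nrow(del)) x else x, ins$pos)
    # shift is based on ancestor-space comparison, so use original x against
    # ancestor-space insertion positions
    k <- findInterval(x, ins$pos)
    x2 <- x2 + ifelse(k >= 1L, cumins[pmax(k, 1L)], 0L)
  }
  x2
}
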