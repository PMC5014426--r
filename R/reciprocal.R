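# Two-layered reciprocal mapping of iLoci between two assemblies: each
# locus set is used as query against the other, and a pair is allelic when
# the two loci are one another's best hits at the identity and coverage
# thresholds. Candidate partners are pre-screened with exact probe k-mers
# so only a handful of alignments is computed per locus.

# locate candidate partner loci for each query locus by exact k-mer probes
kmer_candidates <- function(query_ids, query_seqs, target_iloci, target_genome,
                            n_probes = 5L, probe_k = 24L) {
  probes <- character()
  probe_owner <- character()
  for (i in seq_along(query_ids)) {
    s <- query_seqs[[i]]
    n <- nchar(s)
    if (n < probe_k) next
    npb <- min(n_probes, n - probe_k + 1L)
    starts <- unique(as.integer(round(seq(0L, n - probe_k, length.out = npb))))
    for (st in starts) {
      pb <- s_sub(s, st, st + probe_k)
      if (grepl("N", pb, fixed = TRUE)) next
      probes <- c(probes, pb)
      probe_owner <- c(probe_owner, query_ids[i])
    }
  }
  votes <- list()
  if (!length(probes)) return(votes)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(probes))
  for (chrom in names(target_genome$chromosomes)) {
    loc <- target_iloci[target_iloci$seqid == chrom, , drop = FALSE]
    if (nrow(loc) == 0L) next
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(
      target_genome$chromosomes[[chrom]]))
    starts0 <- unlist(lapply(seq_along(m), function(j) {
      IRanges::start(m[[j]]) - 1L
    }))
    owners <- rep(probe_owner, times = vapply(seq_along(m), function(j) {
      length(m[[j]])
    }, integer(1L)))
    if (!length(starts0)) next
    idx <- findInterval(starts0, loc$start)
    ok <- idx >= 1L & starts0 < loc$end[pmax(idx, 1L)]
    for (h in which(ok)) {
      key <- owners[h]
      votes[[key]] <- c(votes[[key]], loc$id[idx[h]])
    }
  }
  lapply(votes, function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    names(tb)
  })
}

best_hits <- function(query_iloci, target_iloci, query_genome, target_genome,
                      min_identity, min_coverage, max_candidates, n_probes,
                      probe_k, align_params, subset_ids = NULL,
                      aln_cache = NULL) {
  q <- query_iloci
  if (!is.null(subset_ids)) q <- q[q$id %in% subset_ids, , drop = FALSE]
  qseqs <- lapply(seq_len(nrow(q)), function(i) ilocus_seq(query_genome, q[i, ]))
  cand <- kmer_candidates(q$id, qseqs, target_iloci, target_genome,
                          n_probes = n_probes, probe_k = probe_k)
  tmap <- stats::setNames(seq_len(nrow(target_iloci)), target_iloci$id)
  best <- list()
  for (i in seq_len(nrow(q))) {
    qid <- q$id[i]
    cands <- utils::head(cand[[qid]], max_candidates)
    if (is.null(cands) || !length(cands)) next
    hit <- NULL
    for (tid in cands) {
      key <- paste(qid, tid, sep = "|")
      rkey <- paste(tid, qid, sep = "|")
      if (!is.null(aln_cache) && !is.null(aln_cache[[rkey]])) {
        ral <- aln_cache[[rkey]]
        al <- list(identity = ral$identity, coverage_a = ral$coverage_b,
                   coverage_b = ral$coverage_a,
                   ncols = nchar(ral$ops), key = rkey, swapped = TRUE)
      } else {
        tl <- target_iloci[tmap[[tid]], , drop = FALSE]
        aln <- align_pair(qseqs[[i]], ilocus_seq(target_genome, tl),
                          align_params)
        if (!is.null(aln_cache)) aln_cache[[key]] <- aln
        al <- list(identity = aln$identity, coverage_a = aln$coverage_a,
                   coverage_b = aln$coverage_b, ncols = nchar(aln$ops),
                   key = key, swapped = FALSE)
      }
      if (al$identity < min_identity) next
      # glocal-style coverage: the shorter sequence must be (nearly) fully
      # aligned, so a locus split by an insertion in one strain can still
      # pair with the intact locus containing it in the other
      if (max(al$coverage_a, al$coverage_b) < min_coverage) next
      sc <- al$identity * max(al$coverage_a, al$coverage_b)
      if (is.null(hit) || sc > hit$sc ||
          (sc == hit$sc && al$ncols > hit$ncols) ||
          (sc == hit$sc && al$ncols == hit$ncols && tid < hit$tid)) {
        hit <- list(tid = tid, sc = sc, ncols = al$ncols, al = al)
      }
    }
    if (!is.null(hit)) best[[qid]] <- hit
  }
  best
}

#' Reciprocal-best allelic mapping of two iLocus sets
#'
#' Maps iLoci of strain A onto strain B and vice versa; a pair is emitted
#' when the two loci are mutually best hits with identity and coverage at
#' or above the thresholds. Per pair, mismatch / inserted-base /
#' deleted-base counts and densities (per kb of the strain-A locus) are
#' recorded. Unpaired loci are listed as orphans.
#'
#' @param iloci_a,iloci_b `ILocusSet`s of the two strains.
#' @param genome_a,genome_b The corresponding `GenomeAssembly` objects.
#' @param min_identity,min_coverage Pairing thresholds.
#' @param subset_a Optional vector of strain-A iLocus ids to map (the
#'   reverse layer is restricted to their candidate partners). Orphan lists
#'   then refer to the subset only.
#' @param max_candidates,n_probes,probe_k K-mer prescreen tuning.
#' @param align_params Passed to [align_pair].
#' @return List with `pairs` (data.frame: ids, identity, coverages,
#'   variant counts and M/I/D densities), `orphans_a`, `orphans_b`.
#' @export
reciprocal_map <- function(iloci_a, iloci_b, genome_a, genome_b,
                           min_identity = 0.80, min_coverage = 0.80,
                           subset_a = NULL, max_candidates = 2L,
                           n_probes = 5L, probe_k = 24L,
                           align_params = list()) {
  # canonical order: results never depend on input row order
  iloci_a <- iloci_a[order(iloci_a$seqid, iloci_a$start), , drop = FALSE]
  iloci_b <- iloci_b[order(iloci_b$seqid, iloci_b$start), , drop = FALSE]
  acache <- new.env(parent = emptyenv())
  # forward layer: A as query
  fwd <- best_hits(iloci_a, iloci_b, genome_a, genome_b, min_identity,
                   min_coverage, max_candidates, n_probes, probe_k,
                   align_params, subset_ids = subset_a, aln_cache = acache)
  # reverse layer: B as query; restrict to hit targets when subset given
  subset_b <- if (!is.null(subset_a)) {
    unique(vapply(fwd, function(h) h$tid, character(1L)))
  } else NULL
  rev <- best_hits(iloci_b, iloci_a, genome_b, genome_a, min_identity,
                   min_coverage, max_candidates, n_probes, probe_k,
                   align_params, subset_ids = subset_b, aln_cache = acache)
  rows <- list()
  amap <- stats::setNames(seq_len(nrow(iloci_a)), iloci_a$id)
  for (aid in names(fwd)) {
    bid <- fwd[[aid]]$tid
    if (is.null(rev[[bid]]) || rev[[bid]]$tid != aid) next
    key <- paste(aid, bid, sep = "|")
    rkey <- paste(bid, aid, sep = "|")
    aln <- acache[[key]]
    if (!is.null(aln)) {
      cnt <- count_variants(aln)
      idy <- aln$identity; ca <- aln$coverage_a; cb <- aln$coverage_b
    } else {
      raln <- acache[[rkey]]
      rcnt <- count_variants(raln)
      cnt <- list(mismatches = rcnt$mismatches,
                  inserted_bases = rcnt$deleted_bases,
                  deleted_bases = rcnt$inserted_bases,
                  insertion_events = rcnt$deletion_events,
                  deletion_events = rcnt$insertion_events)
      idy <- raln$identity; ca <- raln$coverage_b; cb <- raln$coverage_a
    }
    len_a <- iloci_a$end[amap[[aid]]] - iloci_a$start[amap[[aid]]]
    dens <- variant_density(cnt, len_a)
    rows[[length(rows) + 1L]] <- data.frame(
      a_id = aid, b_id = bid, identity = idy,
      coverage_a = ca, coverage_b = cb,
      mismatches = cnt$mismatches, inserted_bases = cnt$inserted_bases,
      deleted_bases = cnt$deleted_bases,
      M = dens$M, I = dens$I, D = dens$D, len_a = len_a,
      reciprocal = TRUE
    )
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else data.frame(
    a_id = character(), b_id = character(), identity = numeric(),
    coverage_a = numeric(), coverage_b = numeric(), mismatches = integer(),
    inserted_bases = integer(), deleted_bases = integer(), M = numeric(),
    I = numeric(), D = numeric(), len_a = integer(), reciprocal = logical())
  rownames(pairs) <- NULL
  ids_a <- if (!is.null(subset_a)) subset_a else iloci_a$id
  ids_b <- if (!is.null(subset_b)) subset_b else iloci_b$id
  list(
    pairs = pairs,
    orphans_a = setdiff(ids_a, pairs$a_id),
    orphans_b = setdiff(ids_b, pairs$b_id)
  )
}

#' Classify a TE insertion as allelic or non-allelic
#'
#' A strain-A TE is allelic when the strain-B region delimited by the
#' B-partners of its nearest partnered flanking iLoci contains a
#' same-family TE of any class; otherwise (or when no flank has a
#' reciprocal partner) it is non-allelic.
#'
#' @param te One-row feature data.frame of the TE in strain A (needs
#'   `seqid`, `start`, `end`, `family`).
#' @param flankset `FlankSet` from [flanking_iloci].
#' @param pairs Pair table from [reciprocal_map].
#' @param iloci_b Strain-B `ILocusSet`.
#' @param te_features_b Strain-B feature data.frame of TEs (kind `"TE"`).
#' @param slack Extension (bp) applied when only one flank is partnered.
#' @return List with `call` (`"allelic"`/`"non-allelic"`), `region`
#'   (B chromosome interval searched or NULL) and `warn` flag.
#' @export
classify_te_allelism <- function(te, flankset, pairs, iloci_b, te_features_b,
                                 slack = 2000L) {
  bmap <- stats::setNames(seq_len(nrow(iloci_b)), iloci_b$id)
  partner_of <- function(ids) {
    for (id in ids) {
      j <- match(id, pairs$a_id)
      if (!is.na(j)) return(pairs$b_id[j])
    }
    NULL
  }
  up_b <- partner_of(flankset$upstream)
  down_b <- partner_of(flankset$downstream)
  if (is.null(up_b) && is.null(down_b)) {
    return(list(call = "non-allelic", region = NULL, warn = TRUE))
  }
  rows <- iloci_b[bmap[c(up_b, down_b)], , drop = FALSE]
  if (length(unique(rows$seqid)) > 1L) {
    return(list(call = "non-allelic", region = NULL, warn = TRUE))
  }
  te_w <- te$end - te$start
  rstart <- min(rows$start)
  rend <- max(rows$end)
  if (is.null(up_b)) rstart <- max(0L, rstart - te_w - slack)
  if (is.null(down_b)) rend <- rend + te_w + slack
  region <- list(seqid = rows$seqid[1L], start = rstart, end = rend)
  tb <- te_features_b[te_features_b$seqid == region$seqid &
                        !is.na(te_features_b$family) &
                        te_features_b$family == te$family, , drop = FALSE]
  hit <- any(tb$start < region$end & tb$end > region$start)
  list(call = if (hit) "allelic" else "non-allelic", region = region,
       warn = FALSE)
}
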