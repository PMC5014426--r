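# Simulation configuration and element templates. The generator emulates
# the study design: an ancestor genome annotated with genes and tDNAs; a
# descendant strain A; and a descendant strain B that is a haploid mosaic
# of ancestor-derived blocks and second-parent blocks carrying extra
# divergence. Elements are planted either ancestrally (inherited by both
# strains), lineage-specifically into one strain, confined to
# second-parent blocks, or at RNAP3 transcription start sites.

NONSTOP_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0)), c("A", "C", "G", "T"), paste0)),
  STOP_CODONS)

random_nonstop_codons <- function(n) {
  paste(sample(NONSTOP_CODONS, n, replace = TRUE), collapse = "")
}

# spacer of n_codons codons carrying exactly `stops` in-frame stop codons,
# the last one at the spacer's very end (so the downstream ORF's maximal
# run starts exactly at the spacer end)
make_spacer <- function(n_codons, stops) {
  at <- sort(c(n_codons, sample(seq_len(n_codons - 1L), stops - 1L)))
  cods <- character(n_codons)
  cods[-at] <- sample(NONSTOP_CODONS, n_codons - stops, replace = TRUE)
  cods[at] <- sample(STOP_CODONS, stops, replace = TRUE)
  paste(cods, collapse = "")
}

# random LTR with the published TG...CA terminal hexamers and a guard so
# the terminal inverted repeat of LTR + ... + LTR is exactly 6 bp
make_ltr_seq <- function(len) {
  stopifnot(len >= 20L)
  body <- s_chars(random_dna(len - 12L))
  ltr <- c(s_chars("TGTAAG"), body, s_chars("CTTACA"))
  # position 7 must not complement position len-6 (1-based)
  if (ltr[7L] == COMP[[ltr[len - 6L]]]) {
    ltr[7L] <- setdiff(c("A", "C", "G", "T"), COMP[[ltr[len - 6L]]])[1L]
  }
  paste(ltr, collapse = "")
}

#' Build an element anatomy template
#'
#' Constructs the sequence of one element family from its anatomical
#' parameters: LTR pair with TG...CA termini (6-bp terminal inverted
#' repeat), primer binding site complementary to the 3' terminus of the
#' supplied tRNA starting 2 nt downstream of the 5' LTR, a two-ORF layout
#' with a stop-bearing spacer, and a polypurine tract abutting the 3' LTR.
#' Guard bases prevent the planted signatures from being accidentally
#' extendable, so the recorded anatomy is the unique ground truth.
#'
#' @param family Family label.
#' @param kind `"full"` (LTR-internal-LTR) or `"solo"` (a single LTR).
#' @param trna_end tRNA 3'-end sequence used for the PBS (>= 15 nt).
#' @param ltr_len LTR length, bp.
#' @param total_len Total element length for `kind = "full"`.
#' @param tsd_len,tsd_offset Target-site duplication geometry applied at
#'   planting time.
#' @param orf1_aa,orf2_aa ORF lengths in codons.
#' @param spacer_len Inter-ORF spacer, bp (multiple of 3).
#' @param spacer_stops In-frame stop codons in the spacer.
#' @param pbs_len,ppt_len PBS match length and PPT purine-run length.
#' @return An `ElementTemplate` list with `element_seq` and an `anatomy`
#'   truth record.
#' @export
make_element_template <- function(family, kind = c("full", "solo"),
                                  trna_end = NULL, ltr_len = 244L,
                                  total_len = 5973L, tsd_len = 5L,
                                  tsd_offset = 0L, orf1_aa = 450L,
                                  orf2_aa = 1100L, spacer_len = 324L,
                                  spacer_stops = 4L, pbs_len = 14L,
                                  ppt_len = 13L) {
  kind <- match.arg(kind)
  ltr <- make_ltr_seq(ltr_len)
  if (kind == "solo") {
    return(structure(list(
      family = family, kind = kind, element_seq = ltr,
      anatomy = list(elem_len = ltr_len, ltr_len = ltr_len, tir_len = 6L,
                     tsd_len = tsd_len, tsd_offset = tsd_offset)
    ), class = "ElementTemplate"))
  }
  stopifnot(!is.null(trna_end), nchar(trna_end) >= pbs_len + 1L,
            spacer_len %% 3L == 0L)
  tl <- nchar(trna_end)
  pbs <- revcomp(s_sub(trna_end, tl - pbs_len, tl))
  ns1 <- random_dna(2L)
  # guard: the base after the PBS must not extend the complementary match
  guard <- setdiff(c("A", "C", "G", "T"),
                   COMP[[substr(trna_end, tl - pbs_len, tl - pbs_len)]])[1L]
  orf1 <- paste0("ATG", random_nonstop_codons(orf1_aa - 1L),
                 sample(STOP_CODONS, 1L))
  spacer <- make_spacer(spacer_len %/% 3L, spacer_stops)
  orf2 <- paste0("ATG", random_nonstop_codons(orf2_aa - 1L),
                 sample(STOP_CODONS, 1L))
  ppt <- paste(sample(c("A", "G"), ppt_len, replace = TRUE), collapse = "")
  fixed <- 2L * ltr_len + 2L + pbs_len + 1L + nchar(orf1) + spacer_len +
    nchar(orf2) + ppt_len
  pad <- total_len - fixed
  stopifnot(pad >= 2L)
  gap1 <- pad %/% 2L
  gap2 <- pad - gap1
  # gap2 ends with a pyrimidine so the PPT run is exactly ppt_len
  g2 <- paste0(random_dna(gap2 - 1L), sample(c("C", "T"), 1L))
  elem <- paste0(ltr, ns1, pbs, guard, random_dna(gap1), orf1, spacer, orf2,
                 g2, ppt, ltr)
  stopifnot(nchar(elem) == total_len)
  structure(list(
    family = family, kind = kind, element_seq = elem,
    anatomy = list(elem_len = total_len, ltr_len = ltr_len, tir_len = 6L,
                   tsd_len = tsd_len, tsd_offset = tsd_offset,
                   pbs_offset = 2L, pbs_len = pbs_len, ppt_len = ppt_len,
                   ppt_offset = 0L, spacer_len = spacer_len,
                   spacer_stops = spacer_stops, orf1_aa = orf1_aa,
                   orf2_aa = orf2_aa)
  ), class = "ElementTemplate")
}

#' Simulation configuration
#'
#' Default rates are the study conditions: per-kb substitution divergence
#' of 2.4 intergenic and 1.2 genic (realized on the strain-B lineage),
#' indel event rates giving roughly 1-2 inserted/deleted bases per kb of
#' intergenic sequence, a second-parent mosaic covering half the genome in
#' blocks of mean 50 kb with 3x divergence, and a TE plan with ancestral
#' elements, lineage-B elements confined to second-parent blocks
#' (the differential-segregation structure) and a few lineage-A solo LTRs.
#'
#' @param seed Master seed; template sequences and all downstream
#'   generation derive from it.
#' @param chrom_lengths Named vector of chromosome lengths, bp.
#' @param ... Overrides for any default field.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chrA = 1000000L,
                                                chrB = 1000000L), ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = chrom_lengths,
    gc = 0.49,
    gene_density = 0.35,       # genes per kb
    gene_len_mean = 1350L, gene_len_sd = 300L, gene_len_min = 300L,
    tdna_density = 0.025,      # tDNAs per kb
    tdna_len = 80L,
    sub_rate_genic = 0.0012, sub_rate_intergenic = 0.0024,
    lineage_a_sub_rate = 0,
    ins_rate = 5e-4, del_rate = 7e-4,   # events per intergenic bp
    genic_indel_factor = 0.3,           # genic indel rate relative to intergenic
    indel_mean_len = 2L, indel_max_len = 50L,
    parent2_fraction = 0.5, parent2_block_mean = 50000L,
    parent2_multiplier = 3,
    te_plan = data.frame(
      family = c("gypA", "ltrA", "gypB", "ltrB", "gypC"),
      template = c("full", "solo", "full", "solo", "solo"),
      count = c(6L, 10L, 8L, 12L, 3L),
      label = c("ancestral", "ancestral", "lineage-B", "lineage-B",
                "lineage-A"),
      placement = c("parent1-blocks", "parent1-blocks", "parent2-blocks",
                    "parent2-blocks", "uniform-intergenic"),
      stringsAsFactors = FALSE
    )
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c(names(cfg), "templates", "trna_end"))
    if (length(bad)) stop("unknown config key: ", bad[1L])
    # whole-object fields are replaced, not merged element-wise
    for (v in intersect(names(over), c("te_plan", "templates", "trna_end",
                                       "chrom_lengths"))) {
      cfg[[v]] <- over[[v]]
      over[[v]] <- NULL
    }
    if (length(over)) cfg <- utils::modifyList(cfg, over)
  }
  stopifnot(all(c(cfg$sub_rate_genic, cfg$sub_rate_intergenic,
                  cfg$ins_rate, cfg$del_rate) <= 0.2),
            cfg$parent2_fraction >= 0, cfg$parent2_fraction <= 1,
            all(cfg$te_plan$count >= 0))
  if (is.null(cfg$trna_end)) {
    set.seed(derive_seed(cfg$seed, "trna"))
    cfg$trna_end <- paste0(random_dna(17L), "CCA")
  }
  if (is.null(cfg$templates)) {
    set.seed(derive_seed(cfg$seed, "templates"))
    cfg$templates <- list()
    for (i in seq_len(nrow(cfg$te_plan))) {
      fam <- cfg$te_plan$family[i]
      if (!is.null(cfg$templates[[fam]])) next
      cfg$templates[[fam]] <- if (cfg$te_plan$template[i] == "solo") {
        make_element_template(fam, "solo", ltr_len = 244L)
      } else {
        make_element_template(fam, "full", trna_end = cfg$trna_end)
      }
    }
  }
  structure(cfg, class = "SimulationConfig")
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields override the defaults of [simulation_config]; a `te_plan`
#' block (list of records) replaces the default plan.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's seed.
#' @return A `SimulationConfig`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "chrom_lengths", "gc", "gene_density", "gene_len_mean",
             "gene_len_sd", "gene_len_min", "tdna_density", "tdna_len",
             "sub_rate_genic", "sub_rate_intergenic", "lineage_a_sub_rate",
             "ins_rate", "del_rate", "genic_indel_factor", "indel_mean_len",
             "indel_max_len",
             "parent2_fraction", "parent2_block_mean", "parent2_multiplier",
             "te_plan")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("invalid config key: ", bad[1L])
  if (!is.null(y$chrom_lengths)) y$chrom_lengths <- unlist(y$chrom_lengths)
  if (!is.null(y$te_plan)) {
    y$te_plan <- do.call(rbind, lapply(y$te_plan, as.data.frame))
  }
  if (!is.null(seed)) y$seed <- as.integer(seed)
  do.call(simulation_config, y)
}
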