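# Interval loci (iLoci): an ordered partition of each chromosome into
# merged-feature intervals and the intergenic gaps between them. The
# partition is exact: iLocus lengths sum to the chromosome length.

#' Partition annotated genomes into iLoci
#'
#' Overlapping or book-ended features merge into a single feature iLocus
#' (member ids preserved); the gaps between feature iLoci become intergenic
#' iLoci. Input feature order never changes the output.
#'
#' @param features Feature data.frame (0-based half-open).
#' @param genome A `GenomeAssembly`; every chromosome is partitioned, also
#'   those without features.
#' @return An `ILocusSet`: data.frame with `id`, `seqid`, `start`, `end`,
#'   `class` (`"feature"`/`"intergenic"`) and list-column `members`, sorted
#'   by chromosome then start.
#' @export
build_iloci <- function(features, genome) {
  validate_features(features, genome)
  lens <- chrom_lengths(genome)
  out <- list()
  for (chrom in names(lens)) {
    n <- lens[[chrom]]
    f <- features[features$seqid == chrom, , drop = FALSE]
    f <- f[order(f$start, f$end, f$id), , drop = FALSE]
    if (nrow(f)) {
      ir <- IRanges::IRanges(start = f$start + 1L, end = f$end)
      red <- IRanges::reduce(ir)   # merges overlapping and adjacent
      ov <- IRanges::findOverlaps(ir, red)
      members <- split(f$id[S4Vectors::queryHits(ov)],
                       S4Vectors::subjectHits(ov))
      fs <- IRanges::start(red) - 1L
      fe <- IRanges::end(red)
    } else {
      fs <- integer()
      fe <- integer()
      members <- list()
    }
    starts <- integer()
    ends <- integer()
    cls <- character()
    mem <- list()
    cursor <- 0L
    for (i in seq_along(fs)) {
      if (fs[i] > cursor) {
        starts <- c(starts, cursor); ends <- c(ends, fs[i])
        cls <- c(cls, "intergenic"); mem <- c(mem, list(character()))
      }
      starts <- c(starts, fs[i]); ends <- c(ends, fe[i])
      cls <- c(cls, "feature"); mem <- c(mem, list(members[[as.character(i)]]))
      cursor <- fe[i]
    }
    if (cursor < n) {
      starts <- c(starts, cursor); ends <- c(ends, n)
      cls <- c(cls, "intergenic"); mem <- c(mem, list(character()))
    }
    out[[chrom]] <- data.frame(
      id = sprintf("%s_iL%04d", chrom, seq_along(starts)),
      seqid = chrom, start = starts, end = ends, class = cls,
      stringsAsFactors = FALSE
    )
    out[[chrom]]$members <- mem
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ILocusSet", class(res))
  res
}

#' Flanking iLoci of a TE insertion
#'
#' Returns the nearest `k` iLoci strictly on each side of the TE interval;
#' iLoci overlapping the TE interval (including the TE's own feature
#' iLocus) are never listed. Near a chromosome end fewer than `k` may be
#' returned and the shortfall is flagged.
#'
#' @param iloci An `ILocusSet`.
#' @param te_seqid,te_start,te_end TE interval (0-based half-open).
#' @param k Number of flanking iLoci per side.
#' @param te_id Id recorded in the result.
#' @return A `FlankSet`: list with `te_id`, `upstream` and `downstream`
#'   (iLocus ids, nearest first) and `short` flag.
#' @export
flanking_iloci <- function(iloci, te_seqid, te_start, te_end, k = 2L,
                           te_id = NA_character_) {
  stopifnot(k >= 1L)
  loc <- iloci[iloci$seqid == te_seqid, , drop = FALSE]
  if (nrow(loc) == 0L) stop("TE interval on unknown chromosome: ", te_seqid)
  chrom_len <- max(loc$end)
  if (te_start < 0L || te_end > chrom_len || te_start >= te_end) {
    stop(sprintf("TE interval [%d,%d) outside genome on %s",
                 te_start, te_end, te_seqid))
  }
  up <- loc[loc$end <= te_start, , drop = FALSE]
  up <- up[order(up$end, decreasing = TRUE), , drop = FALSE]
  down <- loc[loc$start >= te_end, , drop = FALSE]
  down <- down[order(down$start), , drop = FALSE]
  list(
    te_id = te_id,
    upstream = utils::head(up$id, k),
    downstream = utils::head(down$id, k),
    short = nrow(up) < k || nrow(down) < k
  )
}

# extract the sequence of one iLocus row
ilocus_seq <- function(genome, ilocus_row) {
  genome_subseq(genome, ilocus_row$seqid, ilocus_row$start, ilocus_row$end)
}

#' Export an ILocusSet as GFF3
#'
#' @param iloci An `ILocusSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_iloci_gff3 <- function(iloci, path) {
  feats <- feature_table(
    seqid = iloci$seqid, start = iloci$start, end = iloci$end,
    strand = ".", kind = "other", id = iloci$id, type = "region"
  )
  write_gff3(feats, path)
}
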