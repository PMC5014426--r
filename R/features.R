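# Feature records and GFF3 I/O.
#
# Features are plain data.frames with columns:
#   seqid   chromosome id
#   start   0-based inclusive start
#   end     0-based exclusive end (half-open)
#   strand  "+", "-" or "."
#   kind    one of FEATURE_KINDS
#   family  optional TE family label (NA otherwise)
#   id      unique feature id
#   type    original GFF3 type (preserved for round trips)

#' Closed set of feature kinds
#' @export
FEATURE_KINDS <- c("gene", "tDNA", "rDNA5S", "ncRNA", "TE", "other")

#' Mapping from GFF3 type column to feature kind
#'
#' Unlisted types map to `"other"`.
#' @export
GFF3_KIND_MAP <- c(
  gene = "gene", mRNA = "gene", CDS = "gene", pseudogene = "gene",
  tRNA = "tDNA", tRNA_gene = "tDNA", tRNA_pseudogene = "tDNA",
  rRNA_5S = "rDNA5S", rRNA = "rDNA5S",
  ncRNA = "ncRNA", snRNA = "ncRNA", snoRNA = "ncRNA", ncRNA_gene = "ncRNA",
  transposable_element = "TE", mobile_genetic_element = "TE",
  repeat_region = "TE", long_terminal_repeat = "TE", LTR_retrotransposon = "TE",
  solo_LTR = "TE", LINE_element = "TE"
)

#' Build a feature table
#'
#' @param seqid,start,end,strand,kind,family,id Column vectors; `start`/`end`
#'   are 0-based half-open.
#' @param type Original GFF3 type; defaults to the kind.
#' @return A feature data.frame.
#' @export
feature_table <- function(seqid, start, end, strand = ".", kind = "other",
                          family = NA_character_, id = NULL, type = NULL) {
  n <- length(seqid)
  if (is.null(id)) id <- sprintf("feat%05d", seq_len(n))
  df <- data.frame(
    seqid = as.character(seqid),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    kind = rep_len(as.character(kind), n),
    family = rep_len(as.character(family), n),
    id = as.character(id),
    type = rep_len(as.character(type %||% kind), n),
    stringsAsFactors = FALSE
  )
  validate_features(df)
  df
}

validate_features <- function(df, genome = NULL) {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1L]
    stop(sprintf("feature '%s': end (%d) <= start (%d)",
                 df$id[bad], df$end[bad], df$start[bad]))
  }
  if (!all(df$kind %in% FEATURE_KINDS)) {
    stop("unknown feature kind: ", setdiff(df$kind, FEATURE_KINDS)[1L])
  }
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    unknown <- setdiff(df$seqid, names(lens))
    if (length(unknown)) stop("feature on unknown chromosome: ", unknown[1L])
    over <- df$end > lens[df$seqid] | df$start < 0L
    if (any(over)) {
      bad <- which(over)[1L]
      stop(sprintf("feature '%s' [%d,%d) outside chromosome %s (length %d)",
                   df$id[bad], df$start[bad], df$end[bad], df$seqid[bad],
                   lens[[df$seqid[bad]]]))
    }
  }
  invisible(df)
}

#' Read a GFF3 file into a feature table
#'
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open at
#' this boundary. The GFF3 type column is mapped to a feature kind via
#' [GFF3_KIND_MAP]; features on chromosomes absent from `genome` are an
#' error.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `GenomeAssembly` used to validate chromosome ids
#'   and bounds.
#' @return A feature data.frame (see [feature_table]).
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(feature_table(character(), integer(), integer())[0L, ])
  }
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  kind <- unname(GFF3_KIND_MAP[type])
  kind[is.na(kind)] <- "other"
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
  ids[is.na(ids) | ids == ""] <- sprintf("feat%05d", which(is.na(ids) | ids == ""))
  fam <- if ("family" %in% names(mc)) as.character(mc$family) else NA_character_
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind,
    family = rep_len(fam, length(gr)),
    id = ids,
    type = type,
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  validate_features(df, genome)
  df
}

#' Write a feature table to GFF3
#'
#' Converts internal 0-based half-open coordinates back to GFF3 1-based
#' inclusive; `read_gff3(write_gff3(x))` reproduces coordinates exactly.
#'
#' @param features A feature data.frame.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "teloci") {
  validate_features(features)
  strand <- features$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = strand
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$id
  if (!all(is.na(features$family))) S4Vectors::mcols(gr)$family <- features$family
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
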