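# GenomeAssembly: a named set of chromosome sequences for one strain.

#' Construct a GenomeAssembly
#'
#' A light container for a strain's chromosome sequences. Sequences are
#' normalized to uppercase with U mapped to T; only A/C/G/T/N are allowed.
#'
#' @param name Strain label.
#' @param chromosomes Named character vector of DNA sequences; names are
#'   chromosome ids and must be unique.
#' @return An object of class `GenomeAssembly`.
#' @export
genome_assembly <- function(name, chromosomes) {
  stopifnot(is.character(chromosomes), length(chromosomes) >= 1L)
  ids <- names(chromosomes)
  if (is.null(ids) || any(ids == "")) stop("chromosomes must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate chromosome id: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(chromosomes)
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L) stop("empty sequence for chromosome ", ids[i])
    msg <- check_alphabet(seqs[[i]])
    if (!is.null(msg)) stop("chromosome ", ids[i], ": ", msg)
  }
  structure(list(name = name, chromosomes = seqs), class = "GenomeAssembly")
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat("GenomeAssembly '", x$name, "': ", length(x$chromosomes),
      " chromosome(s), ", sum(nchar(x$chromosomes)), " bp total\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of an assembly
#'
#' @param genome A `GenomeAssembly`.
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "GenomeAssembly"))
  vapply(genome$chromosomes, nchar, integer(1L))
}

# fetch sequence of interval [start0, end0) on a chromosome
genome_subseq <- function(genome, chrom, start0, end0) {
  seq <- genome$chromosomes[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  n <- nchar(seq)
  if (start0 < 0 || end0 > n || start0 > end0) {
    stop(sprintf("interval [%d,%d) out of range for %s (length %d)",
                 start0, end0, chrom, n))
  }
  s_sub(seq, start0, end0)
}

#' Read a FASTA file into a GenomeAssembly
#'
#' Headers must be unique; sequences are uppercased, U is mapped to T, and
#' any character outside A/C/G/T/N is rejected with its position.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param name Strain label; defaults to the file name without extension.
#' @return A `GenomeAssembly`.
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header: ", ids[duplicated(ids)][1L])
  }
  if (any(Biostrings::width(ss) == 0L)) {
    stop("empty FASTA record: ", ids[Biostrings::width(ss) == 0L][1L])
  }
  seqs <- as.character(ss)
  names(seqs) <- ids
  genome_assembly(name %||% tools::file_path_sans_ext(basename(path)), seqs)
}

#' Write a GenomeAssembly to FASTA
#'
#' @param genome A `GenomeAssembly`.
#' @param path Output path.
#' @param width Line wrap width (bp).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "GenomeAssembly"))
  ss <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
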