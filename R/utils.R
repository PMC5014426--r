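# Internal string/sequence helpers. All genomic coordinates inside the
# package are 0-based half-open; conversion to 1-based inclusive happens
# only at FASTA/GFF3/BED boundaries.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over the alphabet A/C/G/T/N.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# complement of a character vector of single bases
comp_bases <- function(b) unname(COMP[b])

#' Random DNA sequence
#'
#' @param n Length in bp.
#' @param gc GC content in `[0, 1]`.
#' @return A character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# substring in 0-based half-open coordinates
s_sub <- function(x, start0, end0) {
  if (end0 <= start0) return("")
  substr(x, start0 + 1L, end0)
}

# split a sequence into a character vector of single bases
s_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# fast GC fraction
gc_fraction <- function(x) {
  b <- s_chars(x)
  mean(b %in% c("G", "C"))
}

# validate a DNA string, returning NULL or a message naming the first
# offending character and its 1-based position
check_alphabet <- function(x, allow_n = TRUE) {
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- regexpr(sprintf("[^%s]", allowed), x)
  if (bad > 0) {
    sprintf("invalid character '%s' at position %d", substr(x, bad, bad), bad)
  } else NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic integer sub-seed derived from a master seed and a tag;
# kept below 2^31 - 1
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  (as.integer(seed) * 1009L + as.integer(h %% 1000003L)) %% 2147483L + 1L
}
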