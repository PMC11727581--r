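#' Reverse complement of a nucleotide string
#'
#' @param x a single character string over the DNA alphabet (case preserved,
#'   `N` allowed).
#' @return the reverse-complemented string.
#' @examples
#' revcomp("GATTACA")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", x))))
}

# byte length; equals the base count for the ASCII sequences used throughout,
# and unlike nchar(type = "chars") does not rescan multi-megabyte strings
nbytes <- function(x) nchar(x, type = "bytes")

# 0-based half-open slice of one chromosome, clamped to [0, length).
seq_slice <- function(genome, chrom, start, end) {
  s <- genome[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  L <- nbytes(s)
  start <- max(0L, as.integer(start))
  end <- min(L, as.integer(end))
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

#' Read a genome FASTA into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; sequence names are
#' truncated at the first whitespace, matching common chromosome naming.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per sequence.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
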