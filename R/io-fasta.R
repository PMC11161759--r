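#' Read genome sequences from FASTA
#'
#' Loads sequences with [Biostrings::readDNAStringSet()], uppercases
#' them and collapses any non-ACGTN letter (other IUPAC ambiguity codes
#' included) to `N`. Sequence names are truncated at the first
#' whitespace, as aligners do.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGTN]", "N", chr)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(seqs)
  if (any(Biostrings::width(out) < 1L)) stop("FASTA '", path, "': empty sequence")
  out
}

#' Write genome sequences to FASTA
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
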