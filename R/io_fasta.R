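#' Read a genome FASTA
#'
#' Sequences are uppercased on read (the pipeline is case-insensitive) and
#' returned as a named [Biostrings::DNAStringSet].  Sequence names are taken up
#' to the first whitespace, matching common chromosome-naming practice.
#'
#' @param path path to a (plain-text) FASTA file.
#' @return named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    config_error("duplicate sequence name in %s: %s", path,
                 names(x)[duplicated(names(x))][1])
  # uppercase internal representation
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write sequences as FASTA
#'
#' Inverse of [read_fasta()] up to line wrapping.
#'
#' @param seqs named `DNAStringSet` (or coercible character vector).
#' @param path output path.
#' @param width line width, bp.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
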