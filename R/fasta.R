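#' Read and write protein FASTA
#'
#' Thin wrappers around Biostrings handling multi-record, line-wrapped FASTA.
#' `read_protein_fasta` returns a named character vector of upper-case
#' sequences; records containing gap or stop characters are rejected with a
#' named error, and non-standard residues error in strict mode or are dropped
#' in lenient mode (matching the scanner's sanitization).
#'
#' @param path FASTA file path.
#' @param lenient drop non-standard residues instead of erroring.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path, lenient = FALSE) {
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no records in FASTA: ", path, call. = FALSE)
  seqs <- as.character(set)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  out <- vapply(seq_along(seqs), function(i) {
    sanitize_residues(seqs[[i]], lenient = lenient,
                      what = paste0("record '", ids[i], "'"))
  }, character(1))
  stats::setNames(out, ids)
}

#' @rdname read_protein_fasta
#' @param seqs named character vector of sequences.
#' @param width line-wrap width.
#' @export
write_protein_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
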