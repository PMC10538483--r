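# FASTA I/O, thin wrappers over Biostrings (plain or gzipped files).

#' Read a FASTA file
#'
#' @param path Path to a FASTA file, plain or gzipped.
#' @return Named character vector of uppercased sequences, in file order.
#'   Non-ACGT characters (e.g. N runs) are passed through; splitting happens
#'   in [particular_density()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e)
                  stop(sprintf("failed to parse FASTA '%s': %s", path,
                               conditionMessage(e)), call. = FALSE))
  if (length(x) == 0L) stop(sprintf("FASTA file '%s' contains no records", path))
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
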