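#' Read sequencing reads from a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of upper-case DNA sequences.
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write reads to a FASTA file
#'
#' @param reads Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  stopifnot(is.character(reads), !is.null(names(reads)))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- names(reads)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @keywords internal
write_tsv <- function(df, path, na = "NA") {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = na)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
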