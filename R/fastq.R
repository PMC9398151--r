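#' Read single-end FASTQ into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; returns plain
#' character sequences named by read id (first whitespace token of the
#' header).
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads as 4-line FASTQ records with constant quality
#'
#' The simulator emits constant Phred+33 qualities (default `I`, Q40);
#' quality profiles are not modeled.
#'
#' @param reads named character vector (names become read ids; unnamed
#'   reads are numbered `read000001`...).
#' @param path output path.
#' @param qual_char single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  ids <- names(reads)
  if (is.null(ids))
    ids <- sprintf("read%06d", seq_along(reads))
  quals <- strrep(qual_char, nchar(reads))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads))
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", quals), con)
  invisible(path)
}
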