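#' Read and write sequence and table files
#'
#' Thin wrappers around Biostrings readers/writers and base TSV IO so every
#' pipeline artifact round-trips through standard plain-text formats.
#' FASTA is wrapped at 80 columns; FASTQ uses Sanger/Phred+33 qualities.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @param qualities optional character vector of per-read quality strings;
#'   defaults to constant high quality ("I", Q40).
#' @return `read_fasta()`/`read_fastq()` return a named character vector;
#'   the writers return `path` invisibly.
#' @examples
#' fp <- tempfile(fileext = ".fasta")
#' write_fasta(c(g1 = "ACGTACGT"), fp)
#' read_fasta(fp)
#' @name seq_io
NULL

#' @rdname seq_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' @rdname seq_io
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' @rdname seq_io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' @rdname seq_io
#' @export
write_fastq <- function(seqs, path, qualities = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(qualities))
    qualities <- strrep("I", nchar(seqs))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qualities))
  invisible(path)
}

#' @rdname seq_io
#' @param x data frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname seq_io
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
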