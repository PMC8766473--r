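#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames runif
#' @importFrom utils read.delim write.table modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

## split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

seq_collapse <- function(x) paste0(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character scalars over the alphabet `A,C,G,T,N`.
#'
#' @param x DNA string.
#' @return Reverse-complemented string.
#' @export
#' @examples
#' revcomp("ATGC")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

validate_dna <- function(x, allow = c(DNA_BASES, "N"), what = "sequence") {
  bad <- setdiff(unique(seq_chars(x)), allow)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-DNA characters: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Read a FASTA file as named uppercase character strings
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(set)), names(set))
}

#' Write named sequences to a FASTA file
#' @param seqs Named character vector of DNA strings.
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
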