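#' Codon translation table
#'
#' Builds the codon-to-amino-acid map used throughout the package. The default
#' is the vertebrate mitochondrial code (NCBI transl_table 2), under which
#' `ATA` encodes Met, `TGA` encodes Trp, and `AGA`/`AGG` are stop codons, so
#' the stop set is `{TAA, TAG, AGA, AGG}`. Codes are taken from
#' [Biostrings::getGeneticCode()], never hard-coded, so synonymous-family
#' degeneracies always derive from the active table.
#'
#' @param code_id Genetic code identifier accepted by
#'   [Biostrings::getGeneticCode()]; `"2"` (alias `"vert-mito"`) is the
#'   vertebrate mitochondrial code, `"1"` the standard code.
#' @return An object of class `codon_table`: list with `code_id`, `map`
#'   (named character, 64 codons to one-letter amino acids, `*` for stop),
#'   `stops` (character vector), and `families` (list of synonymous families
#'   keyed by amino acid).
#' @export
#' @examples
#' ct <- codon_table()
#' ct$map[["ATA"]]   # "M" under the vertebrate mitochondrial code
#' ct$stops
codon_table <- function(code_id = "vert-mito") {
  id <- switch(code_id, "vert-mito" = "2", "standard" = "1", code_id)
  map <- Biostrings::getGeneticCode(id)
  stopifnot(length(map) == 64L)
  stops <- names(map)[map == "*"]
  aas <- setdiff(unique(map), "*")
  families <- lapply(setNames(aas, aas), function(a) names(map)[map == a])
  structure(list(code_id = id, map = map, stops = stops, families = families),
            class = "codon_table")
}

is_stop <- function(codon, code) codon %in% code$stops

translate_codon <- function(codon, code) {
  aa <- code$map[codon]
  if (any(is.na(aa))) stop("not a codon: ", paste(codon[is.na(aa)], collapse = ","))
  unname(aa)
}

## all 9 single-nucleotide neighbours of a codon
codon_neighbours <- function(codon) {
  ch <- seq_chars(codon)
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, ch[pos])) {
      mut <- ch
      mut[pos] <- b
      out <- c(out, seq_collapse(mut))
    }
  }
  out
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf("<codon_table> NCBI transl_table %s; stops: %s\n",
              x$code_id, paste(x$stops, collapse = " ")))
  invisible(x)
}
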