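## Base composition and strand skews per region class (whole genome,
## concatenated PCGs, tRNAs, rRNAs, control region).

#' Base composition and AT/GC skew of one sequence
#'
#' Counts are taken over `A,C,G,T` (`N` excluded from every denominator).
#' Skews are computed on raw counts: `AT skew = (A - T)/(A + T)`,
#' `GC skew = (G - C)/(G + C)`; a zero denominator yields `NA` (undefined),
#' never 0. Percentages are full precision; use [round_half_even()] with 2
#' digits for display.
#'
#' @param sequence DNA string.
#' @param region_class Label stored in the profile (`genome`, `PCG`, `tRNA`,
#'   `rRNA`, `CR`, or any user label).
#' @return One-row `data.frame`: `region_class`, `length_bp`, `pct_A`,
#'   `pct_T`, `pct_G`, `pct_C`, `gc_content`, `at_skew`, `gc_skew`.
#' @export
#' @examples
#' composition_profile("AATGC")  # at_skew 1/3, gc_skew 0
composition_profile <- function(sequence, region_class = "genome") {
  if (is.null(sequence) || !nzchar(sequence)) stop("empty sequence", call. = FALSE)
  validate_dna(sequence)
  ch <- seq_chars(toupper(sequence))
  counts <- vapply(DNA_BASES, function(b) sum(ch == b), integer(1))
  tot <- sum(counts)
  if (tot == 0L) stop("sequence is all N", call. = FALSE)
  A <- counts[["A"]]; C <- counts[["C"]]; G <- counts[["G"]]; T <- counts[["T"]]
  skew <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(region_class = region_class,
             length_bp = nchar(sequence),
             pct_A = 100 * A / tot, pct_T = 100 * T / tot,
             pct_G = 100 * G / tot, pct_C = 100 * C / tot,
             gc_content = 100 * (G + C) / tot,
             at_skew = skew(A - T, A + T),
             gc_skew = skew(G - C, G + C),
             stringsAsFactors = FALSE)
}

#' Round half to even at a given number of decimals
#'
#' Display rounding used for composition tables (base R `round()` already
#' implements IEC 60559 round-half-even; this wrapper names the intent).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_even <- function(x, digits = 2L) round(x, digits)

## concatenated reference-strand subsequence of all features of one class
class_sequence <- function(record, gene_class) {
  f <- record$features
  f <- f[f$gene_class == gene_class, , drop = FALSE]
  if (nrow(f) == 0L) return(NULL)
  L <- nchar(record$sequence)
  if (max(f$end) > L) stop("feature exceeds sequence bounds", call. = FALSE)
  seq_collapse(substring(record$sequence, f$start, f$end))
}

#' Composition profiles per region class
#'
#' Whole-genome profile plus one profile per gene class present in the
#' record. Class subsequences are extracted by coordinates and concatenated
#' in genomic order; every feature contributes its reference (plus) strand
#' sequence regardless of coding strand, and bases inside overlaps are
#' counted once per feature they belong to (concatenation semantics). The
#' single-strand convention is what makes whole-genome and per-class skews
#' mutually comparable.
#'
#' @param record A `mitogenome_record` with sequence.
#' @return `data.frame` of profiles, one row per class, `genome` first. The
#'   class labels are `genome`, `PCG`, `tRNA`, `rRNA`, `CR`.
#' @export
region_profiles <- function(record) {
  stopifnot(inherits(record, "mitogenome_record"))
  if (is.null(record$sequence)) stop("record has no sequence", call. = FALSE)
  out <- list(composition_profile(record$sequence, "genome"))
  labels <- c(PCG = "PCG", tRNA = "tRNA", rRNA = "rRNA", control_region = "CR")
  for (cls in names(labels)) {
    s <- class_sequence(record, cls)
    if (!is.null(s)) out[[length(out) + 1L]] <- composition_profile(s, labels[[cls]])
  }
  do.call(rbind, out)
}
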