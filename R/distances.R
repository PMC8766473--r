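## Uncorrected p-distance and variable-site counting on aligned sequences.

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

check_aligned <- function(seqs) {
  if (length(seqs) < 1L) stop("no sequences", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences are not equal length", call. = FALSE)
  for (s in seqs) validate_dna(toupper(s), allow = ALN_ALPHABET, what = "aligned sequence")
  invisible(lens[1L])
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among compared sites. Sites with a gap or
#' `N` in either sequence are excluded (pairwise deletion, the default and
#' only mode for a two-sequence comparison). An optional Jukes-Cantor
#' correction is available but not the default.
#'
#' @param a,b Equal-length aligned DNA strings (alphabet `A,C,G,T,N,-`).
#' @param model `"p"` (default, uncorrected) or `"jc"`.
#' @return Numeric distance.
#' @export
#' @examples
#' p_distance("ACGTACGTAC", "ACGTACGTAT")  # 0.1
p_distance <- function(a, b, model = c("p", "jc")) {
  model <- match.arg(model)
  check_aligned(c(a, b))
  ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
  usable <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (!any(usable)) stop("zero comparable sites", call. = FALSE)
  p <- sum(ca[usable] != cb[usable]) / sum(usable)
  if (model == "jc") jc_correct(p) else p
}

#' Pairwise distance matrix of an aligned set
#'
#' @param seqs Named character vector of equal-length aligned sequences (or
#'   a path handled by [read_fasta()] first by the caller).
#' @param model `"p"` or `"jc"`.
#' @param deletion `"pairwise"` (sites dropped per pair) or `"complete"`
#'   (columns with any gap/`N` dropped once for the whole set).
#' @return Symmetric numeric matrix with the sequence names.
#' @export
distance_matrix <- function(seqs, model = c("p", "jc"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model); deletion <- match.arg(deletion)
  check_aligned(seqs)
  if (deletion == "complete") {
    mat <- do.call(rbind, lapply(seqs, function(s) seq_chars(toupper(s))))
    good <- apply(mat, 2L, function(col) all(col %in% DNA_BASES))
    if (!any(good)) stop("zero comparable sites after complete deletion", call. = FALSE)
    seqs <- apply(mat[, good, drop = FALSE], 1L, seq_collapse)
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- p_distance(seqs[[i]], seqs[[j]], model = model)
    }
  }
  d
}

#' Number of variable sites in an aligned set
#'
#' Columns with at least two distinct states among `A,C,G,T` (gaps and `N`
#' are ignored; a column whose only variation involves gaps is not counted).
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Integer count.
#' @export
#' @examples
#' variable_sites(c(x = "AAC", y = "AG-"))  # 1
variable_sites <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  check_aligned(seqs)
  mat <- do.call(rbind, lapply(seqs, function(s) seq_chars(toupper(s))))
  sum(apply(mat, 2L, function(col) {
    states <- unique(col[col %in% DNA_BASES])
    length(states) >= 2L
  }))
}
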