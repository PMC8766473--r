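## Start/stop codon extraction, codon counting, RSCU and amino-acid
## abundance under a chosen genetic code (default: vertebrate mitochondrial).

#' Extract start codon, stop token and in-frame codons of one gene
#'
#' The coding sequence is taken from the record's reference strand and
#' reverse-complemented first for minus-strand genes. The start codon is
#' whatever the first in-frame triplet is (reported, not validated against a
#' whitelist: non-ATG starts such as ATC/ATT/ATA occur). A residual of 1-2 nt
#' after the last full codon is an incomplete stop, reported in the
#' `"T(AA)"` style and excluded from the codon list; otherwise the terminal
#' full codon is the stop token. Internal stop codons are recorded as
#' warnings, not errors.
#'
#' @param record A `mitogenome_record` with sequence.
#' @param gene Name of a protein-coding gene in the record.
#' @param code A [codon_table()].
#' @return List: `gene`, `start_codon`, `stop_codon`,
#'   `incomplete_stop` (flag), `codons` (character vector excluding the
#'   stop), `internal_stops` (1-based codon indices of in-frame stops before
#'   the terminus, if any).
#' @export
extract_codons <- function(record, gene, code = codon_table()) {
  stopifnot(inherits(record, "mitogenome_record"))
  if (is.null(record$sequence)) stop("record has no sequence", call. = FALSE)
  f <- record$features
  row <- f[f$gene == gene, , drop = FALSE]
  if (nrow(row) == 0L) stop("no such gene: ", gene, call. = FALSE)
  row <- row[1L, ]
  if (row$gene_class != "PCG") stop(gene, " is not a protein-coding gene", call. = FALSE)
  cds <- substr(record$sequence, row$start, row$end)
  if (row$strand == "-") cds <- revcomp(cds)
  if (nchar(cds) < 6L) stop("CDS shorter than 6 nt for ", gene, call. = FALSE)
  n_full <- nchar(cds) %/% 3L
  rem <- nchar(cds) %% 3L
  codons <- substring(cds, 3L * (seq_len(n_full) - 1L) + 1L, 3L * seq_len(n_full))
  if (rem > 0L) {
    stop_codon <- incomplete_stop_token(substr(cds, 3L * n_full + 1L, nchar(cds)))
    incomplete <- TRUE
    body <- codons
  } else {
    stop_codon <- codons[n_full]
    incomplete <- FALSE
    body <- codons[-n_full]
  }
  internal <- which(body %in% code$stops)
  if (length(internal)) {
    warning(sprintf("%s: internal stop codon(s) at codon position(s) %s",
                    gene, paste(internal, collapse = ",")), call. = FALSE)
  }
  list(gene = gene, start_codon = body[1L], stop_codon = stop_codon,
       incomplete_stop = incomplete, codons = body, internal_stops = internal)
}

#' Codon counts over the protein-coding genes of a record
#'
#' Concatenates the in-frame codons of the requested PCGs (stops excluded,
#' see [extract_codons()]) and tabulates them over all 64 codons.
#'
#' @param record A `mitogenome_record` with sequence.
#' @param genes PCG names, default all PCGs in the record.
#' @param code A [codon_table()].
#' @return Named integer vector of length 64.
#' @export
codon_counts <- function(record, genes = NULL, code = codon_table()) {
  f <- record$features
  if (is.null(genes)) genes <- f$gene[f$gene_class == "PCG"]
  all_codons <- unlist(lapply(genes, function(g) extract_codons(record, g, code)$codons))
  tab <- table(factor(all_codons, levels = names(code$map)))
  setNames(as.integer(tab), names(tab))
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = n_fam * X_c / sum(X_c' over the synonymous family)`, i.e. the
#' observed count divided by the family-uniform expectation. Families are
#' defined by the active genetic code; stop codons are excluded. A family
#' with zero total leaves its codons' RSCU undefined (`NA`). Within each
#' family with nonzero total, RSCU sums to the family degeneracy.
#'
#' @param counts Named codon counts (any subset of the 64 codons; missing
#'   codons count 0), e.g. from [codon_counts()].
#' @param code A [codon_table()].
#' @return `data.frame`: `codon`, `aa`, `degeneracy`, `count`, `rscu`.
#' @export
#' @examples
#' rscu(c(GCA = 3, GCC = 1))  # Ala family: 3.0, 1.0, 0.0, 0.0
rscu <- function(counts, code = codon_table()) {
  full <- setNames(integer(64), names(code$map))
  if (is.null(names(counts))) stop("counts must be a named vector", call. = FALSE)
  unknown <- setdiff(names(counts), names(full))
  if (length(unknown)) stop("unknown codons: ", paste(unknown, collapse = ","), call. = FALSE)
  full[names(counts)] <- as.integer(counts)
  if (sum(full) == 0L) stop("no codons counted", call. = FALSE)
  rows <- lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    n_fam <- length(fam)
    tot <- sum(full[fam])
    data.frame(codon = fam, aa = aa, degeneracy = n_fam,
               count = as.integer(full[fam]),
               rscu = if (tot > 0L) n_fam * full[fam] / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$aa, out$codon), ]
}

#' Relative amino-acid abundance
#'
#' Frequencies of the encoded amino acids (stops excluded), summing to 1.
#'
#' @inheritParams rscu
#' @return Named numeric vector over all amino acids of the code (zero
#'   frequencies kept), summing to 1.
#' @export
aa_abundance <- function(counts, code = codon_table()) {
  full <- setNames(integer(64), names(code$map))
  full[names(counts)] <- as.integer(counts)
  sense <- setdiff(names(full), code$stops)
  if (sum(full[sense]) == 0L) stop("no sense codons counted", call. = FALSE)
  aa <- vapply(names(code$families), function(a) sum(full[code$families[[a]]]),
               numeric(1))
  aa / sum(aa)
}

#' Start/stop codon table of all PCGs
#'
#' @param record A `mitogenome_record` with sequence.
#' @param code A [codon_table()].
#' @return `data.frame`: `gene`, `start_codon`, `stop_codon`,
#'   `incomplete_stop`.
#' @export
start_stop_table <- function(record, code = codon_table()) {
  f <- record$features
  genes <- f$gene[f$gene_class == "PCG"]
  rows <- lapply(genes, function(g) {
    x <- extract_codons(record, g, code)
    data.frame(gene = g, start_codon = x$start_codon, stop_codon = x$stop_codon,
               incomplete_stop = x$incomplete_stop, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
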