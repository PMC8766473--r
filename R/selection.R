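## Nei-Gojobori (1986) pathway counting of synonymous/nonsynonymous sites and
## differences, with Jukes-Cantor multiple-hit correction.

#' Synonymous/nonsynonymous site counts of one codon (NG86)
#'
#' For each of the three positions, the synonymous fraction is the number of
#' the three possible single-nucleotide changes that are synonymous, divided
#' by the number of changes that do not create a stop codon (changes to stops
#' are excluded from numerator and denominator, the standard NG86 practice).
#' `s` is the sum over positions and `n = 3 - s`, so `s + n == 3` always.
#'
#' @param codon Sense 3-mer.
#' @param code A [codon_table()].
#' @return Named numeric vector `c(s = , n = )`.
#' @export
#' @examples
#' count_sites("TTT")  # s = 1/3 under the vertebrate mitochondrial code
count_sites <- function(codon, code = codon_table()) {
  codon <- toupper(codon)
  if (is.na(code$map[codon])) stop("not a codon: ", codon, call. = FALSE)
  if (is_stop(codon, code)) stop("stop codon has no site counts: ", codon, call. = FALSE)
  aa <- code$map[[codon]]
  ch <- seq_chars(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; nonstop <- 0L
    for (b in setdiff(DNA_BASES, ch[pos])) {
      mut <- ch; mut[pos] <- b
      mcod <- seq_collapse(mut)
      if (is_stop(mcod, code)) next
      nonstop <- nonstop + 1L
      if (code$map[[mcod]] == aa) syn <- syn + 1L
    }
    if (nonstop > 0L) s <- s + syn / nonstop
  }
  c(s = s, n = 3 - s)
}

## classify one single-nucleotide step codon_from -> codon_to
step_type <- function(from, to, code) {
  if (code$map[[from]] == code$map[[to]]) "s" else "n"
}

#' Synonymous/nonsynonymous differences between two codons (NG86)
#'
#' Codons differing at one position are classified directly. For 2-3
#' differences, the synonymous/nonsynonymous split is averaged with equal
#' weight over all orderings of single-nucleotide steps, excluding pathways
#' that pass through a stop codon. If every pathway is blocked by stops, the
#' count falls back to averaging over all pathways (flagged).
#'
#' @param codon_a,codon_b Sense 3-mers.
#' @param code A [codon_table()].
#' @return List: `sd`, `nd` (fractional), `blocked_fallback` (flag).
#' @export
#' @examples
#' count_differences("TTT", "TTC")  # one synonymous difference (Phe/Phe)
count_differences <- function(codon_a, codon_b, code = codon_table()) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (c0 in c(codon_a, codon_b)) {
    if (is.na(code$map[c0])) stop("not a codon: ", c0, call. = FALSE)
    if (is_stop(c0, code)) stop("stop codon in comparison: ", c0, call. = FALSE)
  }
  ch_a <- seq_chars(codon_a); ch_b <- seq_chars(codon_b)
  diff_pos <- which(ch_a != ch_b)
  k <- length(diff_pos)
  if (k == 0L) return(list(sd = 0, nd = 0, blocked_fallback = FALSE))
  paths <- pathway_counts(codon_a, ch_b, diff_pos, code, skip_stops = TRUE)
  fallback <- FALSE
  if (paths$n_paths == 0L) {
    paths <- pathway_counts(codon_a, ch_b, diff_pos, code, skip_stops = FALSE)
    fallback <- TRUE
  }
  list(sd = paths$sd / paths$n_paths, nd = paths$nd / paths$n_paths,
       blocked_fallback = fallback)
}

## walk every ordering of the differing positions, accumulating step types
pathway_counts <- function(from, ch_to, diff_pos, code, skip_stops) {
  perms <- permutations_of(diff_pos)
  sd <- 0; nd <- 0; n_paths <- 0L
  for (ord in perms) {
    cur <- seq_chars(from)
    s_steps <- 0L; n_steps <- 0L; ok <- TRUE
    for (pos in ord) {
      prev <- seq_collapse(cur)
      cur[pos] <- ch_to[pos]
      nxt <- seq_collapse(cur)
      if (is_stop(nxt, code) && skip_stops) { ok <- FALSE; break }
      if (!is_stop(nxt, code) && !is_stop(prev, code)) {
        if (step_type(prev, nxt, code) == "s") s_steps <- s_steps + 1L
        else n_steps <- n_steps + 1L
      } else {
        ## fallback only: steps touching a stop are classified nonsynonymous
        n_steps <- n_steps + 1L
      }
    }
    if (ok) {
      sd <- sd + s_steps; nd <- nd + n_steps; n_paths <- n_paths + 1L
    }
  }
  list(sd = sd, nd = nd, n_paths = n_paths)
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' `d = -(3/4) * log(1 - 4p/3)`; `p >= 3/4` is saturated and yields `NA`.
#'
#' @param p Proportion of differences in `[0, 1]`.
#' @return Corrected distance, or `NA` at saturation.
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka, Ks and Ka/Ks for two aligned coding sequences (NG86)
#'
#' Takes two equal-length in-frame codon lists (the caller aligns; codon
#' pairs where either codon contains a gap, `N`, or is a stop are dropped
#' pairwise). Sites `S` and `N` are the means of the two sequences' per-codon
#' site sums; differences `Sd`, `Nd` come from [count_differences()];
#' `ps = Sd/S`, `pn = Nd/N` are Jukes-Cantor corrected to `Ks`, `Ka`.
#' `Ks == 0` leaves the ratio undefined (`NA`), and `ps` or `pn >= 3/4`
#' flags saturation with undefined distances.
#'
#' @param codons_a,codons_b Equal-length character vectors of codons.
#' @param code A [codon_table()].
#' @param gene Optional gene label carried into the result.
#' @return Object of class `kaks_result`: list with `gene`,
#'   `n_codons_compared`, `S_sites`, `N_sites`, `Sd`, `Nd`, `ps`, `pn`,
#'   `Ks`, `Ka`, `ratio`, `flags`.
#' @export
kaks <- function(codons_a, codons_b, code = codon_table(), gene = NA_character_) {
  if (length(codons_a) != length(codons_b)) {
    stop("codon lists differ in length (caller must align)", call. = FALSE)
  }
  codons_a <- toupper(codons_a); codons_b <- toupper(codons_b)
  clean <- function(x) grepl("^[ACGT]{3}$", x)
  usable <- clean(codons_a) & clean(codons_b) &
    !(codons_a %in% code$stops) & !(codons_b %in% code$stops)
  a <- codons_a[usable]; b <- codons_b[usable]
  if (length(a) == 0L) stop("zero comparable codons", call. = FALSE)
  ## per-codon site counts depend only on the codon: compute once per type
  uniq <- unique(c(a, b))
  site_tab <- vapply(uniq, count_sites, numeric(2), code = code)
  S <- (sum(site_tab["s", a]) + sum(site_tab["s", b])) / 2
  N <- (sum(site_tab["n", a]) + sum(site_tab["n", b])) / 2
  Sd <- 0; Nd <- 0; flags <- character(0)
  for (i in seq_along(a)) {
    if (a[i] == b[i]) next
    d <- count_differences(a[i], b[i], code)
    Sd <- Sd + d$sd; Nd <- Nd + d$nd
    if (d$blocked_fallback) flags <- union(flags, "blocked_pathway_fallback")
  }
  ps <- Sd / S; pn <- Nd / N
  Ks <- jc_correct(ps); Ka <- jc_correct(pn)
  if (is.na(Ks) || is.na(Ka)) flags <- union(flags, "saturated")
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(gene = gene, n_codons_compared = length(a),
                 S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn, Ks = Ks, Ka = Ka, ratio = ratio,
                 flags = flags),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result>%s %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ks=%s Ka=%s Ka/Ks=%s%s\n",
              ifelse(is.na(x$gene), "", paste0(" ", x$gene)),
              x$n_codons_compared, x$S_sites, x$N_sites, x$Sd, x$Nd,
              format(x$Ks, digits = 4), format(x$Ka, digits = 4),
              format(x$ratio, digits = 4),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Per-gene Ka/Ks between two annotated genomes
#'
#' Pairs the in-frame codons of each shared protein-coding gene (trivial
#' equal-length pairing; a length mismatch for a gene is an error, no
#' alignment is attempted) and runs [kaks()].
#'
#' @param record_a,record_b `mitogenome_record`s with sequence.
#' @param genes PCG names; default all PCGs shared by both records.
#' @param code A [codon_table()].
#' @return `data.frame` with one row per gene: `gene`, `n_codons`, `S`, `N`,
#'   `Sd`, `Nd`, `Ks`, `Ka`, `ratio`, `flags`.
#' @export
kaks_table <- function(record_a, record_b, genes = NULL, code = codon_table()) {
  pa <- record_a$features$gene[record_a$features$gene_class == "PCG"]
  pb <- record_b$features$gene[record_b$features$gene_class == "PCG"]
  if (is.null(genes)) genes <- intersect(pa, pb)
  rows <- lapply(genes, function(g) {
    ca <- extract_codons(record_a, g, code)$codons
    cb <- extract_codons(record_b, g, code)$codons
    if (length(ca) != length(cb)) {
      stop(sprintf("gene %s: codon counts differ (%d vs %d); align first",
                   g, length(ca), length(cb)), call. = FALSE)
    }
    r <- kaks(ca, cb, code, gene = g)
    data.frame(gene = g, n_codons = r$n_codons_compared, S = r$S_sites,
               N = r$N_sites, Sd = r$Sd, Nd = r$Nd, Ks = r$Ks, Ka = r$Ka,
               ratio = r$ratio,
               flags = paste(r$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
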