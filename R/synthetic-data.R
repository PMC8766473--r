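## Seeded synthetic mitogenome generator: a fully specified stand-in world
## (circular 37-gene vertebrate layout, class-specific base composition,
## planted control-region repeat arrays, controlled synonymous/nonsynonymous
## divergence between genome pairs) so the whole pipeline runs and is
## verifiable without downloads.

#' Path of the packaged 38-row reference gene table
#'
#' Machine-readable transcript of the annotated gene list of the Tupaia
#' nicobarica mitogenome (GenBank MW751815): 13 PCGs, 22 tRNAs, 2 rRNAs and
#' the control region on a 17,164 bp circle. This is the default layout of
#' the generator and the anchor of the package's structural regression tests.
#'
#' @return File path.
#' @export
default_gene_table_path <- function() {
  system.file("extdata", "tupaia_nicobarica_MW751815.tsv",
              package = "mitoarch", mustWork = TRUE)
}

## Per-class base probabilities (A, C, G, T) emulating a treeshrew-like,
## A+T-biased, GC-skew-negative mitogenome.
default_base_probs <- function() {
  list(
    background = c(A = 0.3256, C = 0.2713, G = 0.1454, T = 0.2574),
    tRNA       = c(A = 0.3406, C = 0.2211, G = 0.1703, T = 0.2678),
    rRNA       = c(A = 0.3584, C = 0.2274, G = 0.1869, T = 0.2270),
    control_region = c(A = 0.3323, C = 0.2663, G = 0.1434, T = 0.2572)
  )
}

#' Specification for one synthetic mitogenome
#'
#' @param seed Integer seed; one RNG stream per [generate_genome()] call.
#' @param gene_table Path to a gene-table TSV, or a feature `data.frame`;
#'   defaults to the packaged 38-row vertebrate layout
#'   ([default_gene_table_path()]).
#' @param base_probs Named list of A/C/G/T probability vectors for classes
#'   `background`, `tRNA`, `rRNA`, `control_region` (each summing to 1).
#' @param pcg_codon_usage Sampling weights for protein-coding body codons:
#'   named non-negative vector over sense codons; default uniform over the
#'   60 sense codons of the vertebrate mitochondrial code.
#' @param planted_repeat `NULL`, or `list(motif=, copies=, offset=)`: a
#'   tandem array of `motif` repeated `copies` times (fractional copies keep
#'   a partial final copy) written into the control region starting at
#'   1-based `offset` within the CR. The default plants `CGTACA` 60.3 times
#'   near the CR 3' end, emulating a treeshrew-style repeat array.
#' @param code A [codon_table()].
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(seed = 7L, gene_table = NULL, base_probs = NULL,
                        pcg_codon_usage = NULL, planted_repeat = NULL,
                        code = codon_table()) {
  if (is.null(gene_table)) gene_table <- default_gene_table_path()
  features <- if (is.data.frame(gene_table)) sort_features(gene_table)
              else read_gene_table(gene_table)$features
  probs <- modifyList(default_base_probs(), if (is.null(base_probs)) list() else base_probs)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    stopifnot(abs(sum(p) - 1) < 1e-3, all(p >= 0), all(c("A","C","G","T") %in% names(p)))
    probs[[nm]] <- p / sum(p)  # absorb print-precision slack in stated tables
  }
  sense <- setdiff(names(code$map), code$stops)
  if (is.null(pcg_codon_usage)) {
    pcg_codon_usage <- setNames(rep(1, length(sense)), sense)
  }
  stopifnot(all(names(pcg_codon_usage) %in% sense))
  if (is.null(planted_repeat) && any(features$gene_class == "control_region")) {
    cr <- features[features$gene_class == "control_region", ][1L, ]
    arr_len <- as.integer(round(60.3 * 6))
    if (cr$size >= arr_len + 60L) {
      planted_repeat <- list(motif = "CGTACA", copies = 60.3,
                             offset = cr$size - arr_len - 30L)
    }
  }
  structure(list(seed = as.integer(seed), features = features,
                 base_probs = probs, pcg_codon_usage = pcg_codon_usage,
                 planted_repeat = planted_repeat, code = code),
            class = "genome_spec")
}

sample_bases <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

parse_stop_token <- function(token, code) {
  ## returns list(residual=, complete=) : bases actually written at the 3' end
  if (is.na(token)) return(list(residual = NULL, complete = sample(code$stops, 1L)))
  if (is_incomplete_stop(token)) {
    residual <- sub("\\(.*$", "", token)
    return(list(residual = residual, complete = NULL))
  }
  list(residual = NULL, complete = token)
}

## realized in-frame codons of one PCG read from a base vector (independent
## bookkeeping path, deliberately not extract_codons())
realized_codons <- function(ch, row) {
  cds <- ch[row$start:row$end]
  if (row$strand == "-") cds <- seq_chars(revcomp(seq_collapse(cds)))
  n_full <- length(cds) %/% 3L
  rem <- length(cds) %% 3L
  cod <- vapply(seq_len(n_full), function(i) seq_collapse(cds[(3L*i-2L):(3L*i)]),
                character(1))
  if (rem == 0L) cod[-n_full] else cod
}

#' Generate a synthetic annotated mitogenome
#'
#' Deterministic for a fixed seed. The genome is filled in three passes:
#' (1) background bases from `base_probs$background` over the whole circle;
#' (2) tRNA/rRNA/control-region spans redrawn from their class
#' probabilities, with the planted repeat array written into the CR;
#' (3) protein-coding genes written as in-frame codon strings (declared
#' start codon, body codons sampled from `pcg_codon_usage`, declared stop -
#' incomplete stops write only their residual nucleotides), minus-strand
#' genes reverse-complemented onto the reference. PCGs are written in start
#' order, so where two PCGs overlap the downstream gene's frame wins and the
#' upstream gene's tail (including its stop) is whatever the downstream gene
#' wrote; such genes are listed in the ground truth as `adjusted_tail`.
#' A downstream feature that would overwrite a PCG's start codon makes the
#' layout infeasible and is an error naming the genes.
#'
#' The ground-truth ledger records the realized per-gene codon counts (read
#' back from the final sequence by an independent bookkeeping path), realized
#' start/stop tokens, per-class region coordinates, and the planted repeat's
#' absolute location.
#'
#' @param spec A [genome_spec()].
#' @return List with `record` (a `mitogenome_record`) and `truth` (ledger).
#' @export
#' @examples
#' g <- generate_genome(genome_spec(seed = 7))
#' g$record
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  f <- spec$features
  L <- max(f$end)
  code <- spec$code

  ## feasibility: no feature may overwrite a PCG start codon
  pcg <- f[f$gene_class == "PCG", , drop = FALSE]
  for (i in seq_len(nrow(pcg))) {
    head_lo <- if (pcg$strand[i] == "-") pcg$end[i] - 2L else pcg$start[i]
    head_hi <- if (pcg$strand[i] == "-") pcg$end[i] else pcg$start[i] + 2L
    later <- pcg[pcg$start > pcg$start[i], , drop = FALSE]
    hit <- later[later$start <= head_hi & later$end >= head_lo, , drop = FALSE]
    if (nrow(hit)) {
      stop(sprintf("infeasible layout: %s would overwrite the start codon of %s",
                   hit$gene[1L], pcg$gene[i]), call. = FALSE)
    }
  }

  ch <- sample_bases(L, spec$base_probs$background)

  ## pass 2: non-coding classes
  for (i in which(f$gene_class %in% c("tRNA", "rRNA", "control_region"))) {
    cls <- f$gene_class[i]
    p <- if (cls == "control_region") spec$base_probs$control_region else spec$base_probs[[cls]]
    ch[f$start[i]:f$end[i]] <- sample_bases(f$size[i], p)
  }
  repeat_truth <- NULL
  if (!is.null(spec$planted_repeat)) {
    cr <- f[f$gene_class == "control_region", , drop = FALSE]
    if (nrow(cr) == 0L) stop("planted_repeat requires a control region", call. = FALSE)
    pr <- spec$planted_repeat
    period <- nchar(pr$motif)
    arr_len <- as.integer(round(pr$copies * period))
    abs_start <- cr$start[1L] + pr$offset - 1L
    abs_end <- abs_start + arr_len - 1L
    if (abs_end > cr$end[1L]) stop("planted repeat exceeds control-region bounds", call. = FALSE)
    arr <- seq_chars(strrep(pr$motif, ceiling(arr_len / period)))[seq_len(arr_len)]
    ch[abs_start:abs_end] <- arr
    repeat_truth <- list(motif = pr$motif, period = period,
                         copies = arr_len / period,
                         start = abs_start, end = abs_end)
  }

  ## pass 3: protein-coding genes, start order (downstream overwrites tails)
  sense <- names(spec$pcg_codon_usage)
  for (i in seq_len(nrow(pcg))) {
    row <- pcg[i, ]
    size <- row$size
    stop_tok <- parse_stop_token(row$stop_codon, code)
    start_codon <- if (is.na(row$start_codon) || row$start_codon == "NNN") "ATG" else row$start_codon
    rem <- size %% 3L
    if (rem == 0L && !is.null(stop_tok$residual)) {
      stop(sprintf("gene %s: incomplete stop token but size %d is a codon multiple",
                   row$gene, size), call. = FALSE)
    }
    if (rem > 0L) {
      if (is.null(stop_tok$residual)) stop_tok$residual <- substr("TAA", 1L, rem)
      if (nchar(stop_tok$residual) != rem) {
        stop(sprintf("gene %s: stop token residual inconsistent with size", row$gene),
             call. = FALSE)
      }
      n_body <- size %/% 3L - 1L
      tail_nt <- stop_tok$residual
    } else {
      n_body <- size %/% 3L - 2L
      tail_nt <- stop_tok$complete
    }
    if (n_body < 0L) stop(sprintf("gene %s too short for a coding layout", row$gene),
                          call. = FALSE)
    body <- sample(sense, n_body, replace = TRUE, prob = spec$pcg_codon_usage)
    cds <- paste0(start_codon, paste0(body, collapse = ""), tail_nt)
    stopifnot(nchar(cds) == size)
    if (row$strand == "-") cds <- revcomp(cds)
    ch[row$start:row$end] <- seq_chars(cds)
  }

  ## ground truth read back from the final sequence
  adjusted <- character(0)
  codon_truth <- list(); start_truth <- character(0); stop_truth <- character(0)
  for (i in seq_len(nrow(pcg))) {
    row <- pcg[i, ]
    others <- f[f$gene != row$gene & f$start > row$start &
                  f$start <= row$end & f$gene_class == "PCG", , drop = FALSE]
    if (nrow(others)) adjusted <- c(adjusted, row$gene)
    cod <- realized_codons(ch, row)
    codon_truth[[row$gene]] <- cod
    start_truth[row$gene] <- cod[1L]
    rem <- row$size %% 3L
    stop_truth[row$gene] <- if (rem > 0L) {
      cds <- ch[row$start:row$end]
      if (row$strand == "-") cds <- seq_chars(revcomp(seq_collapse(cds)))
      incomplete_stop_token(seq_collapse(cds[(row$size - rem + 1L):row$size]))
    } else {
      cds <- ch[row$start:row$end]
      if (row$strand == "-") cds <- seq_chars(revcomp(seq_collapse(cds)))
      seq_collapse(cds[(row$size - 2L):row$size])
    }
  }
  all_codons <- unlist(codon_truth, use.names = FALSE)
  counts <- table(factor(all_codons, levels = names(code$map)))

  record <- mitogenome_record(f, sequence = seq_collapse(ch),
                              accession = sprintf("SYNTH-%d", spec$seed),
                              species = "synthetic mitogenome")
  truth <- list(seed = spec$seed,
                base_probs = spec$base_probs,
                codon_counts = setNames(as.integer(counts), names(counts)),
                codons_by_gene = codon_truth,
                start_codons = start_truth,
                stop_codons = stop_truth,
                adjusted_tail = adjusted,
                planted_repeat = repeat_truth)
  list(record = record, truth = truth)
}

#' Specification of a controlled divergence between a genome pair
#'
#' @param seed Integer seed.
#' @param n_syn,n_nonsyn Numbers of synonymous / nonsynonymous
#'   single-nucleotide codon changes to apply (each in a distinct codon, so
#'   pathway counting recovers them exactly).
#' @param genes Target PCG names; default all PCGs of the record.
#' @return Object of class `divergence_spec`.
#' @export
divergence_spec <- function(seed = 1L, n_syn = 0L, n_nonsyn = 0L, genes = NULL) {
  structure(list(seed = as.integer(seed), n_syn = as.integer(n_syn),
                 n_nonsyn = as.integer(n_nonsyn), genes = genes),
            class = "divergence_spec")
}

## single-nucleotide mutations of a codon that are synonymous (type "s") or
## nonsynonymous (type "n"), never creating a stop
codon_mutations <- function(codon, code) {
  aa <- code$map[[codon]]
  muts <- codon_neighbours(codon)
  muts <- muts[!muts %in% code$stops]
  data.frame(to = muts,
             type = ifelse(code$map[muts] == aa, "s", "n"),
             stringsAsFactors = FALSE)
}

#' Apply controlled synonymous/nonsynonymous divergence to a genome
#'
#' Produces a second genome differing from `record` by exactly `n_syn`
#' synonymous and `n_nonsyn` nonsynonymous single-nucleotide changes, each
#' placed in a distinct in-frame codon of a target protein-coding gene,
#' validated against the genetic code at application time, and never
#' creating a stop codon. Codons lying inside a region shared with any other
#' annotated feature are never touched, so every change affects exactly one
#' gene. Minus-strand genes are edited through their reading frame and
#' written back reverse-complemented.
#'
#' @param record A `mitogenome_record` with sequence (e.g. from
#'   [generate_genome()]).
#' @param spec A [divergence_spec()].
#' @param code A [codon_table()].
#' @return List with `record` (the diverged copy) and `truth`, a
#'   `data.frame` listing each change: `gene`, `codon_index`, `from_codon`,
#'   `to_codon`, `type` (`"s"`/`"n"`), `genome_pos`.
#' @export
diverge_pair <- function(record, spec, code = codon_table()) {
  stopifnot(inherits(record, "mitogenome_record"), inherits(spec, "divergence_spec"))
  if (is.null(record$sequence)) stop("record has no sequence", call. = FALSE)
  set.seed(spec$seed)
  f <- record$features
  genes <- spec$genes
  if (is.null(genes)) genes <- f$gene[f$gene_class == "PCG"]
  ch <- seq_chars(record$sequence)

  ## candidate codons: in-frame, sense, not overlapping any other feature
  cands <- list()
  for (g in genes) {
    row <- f[f$gene == g, , drop = FALSE][1L, ]
    if (row$gene_class != "PCG") stop(g, " is not a PCG", call. = FALSE)
    n_body <- if (row$size %% 3L == 0L) row$size %/% 3L - 1L else row$size %/% 3L
    others <- f[f$gene != g, , drop = FALSE]
    for (idx in seq_len(n_body)) {
      ## genomic span of codon idx (1-based within CDS)
      if (row$strand == "+") {
        lo <- row$start + 3L * (idx - 1L); hi <- lo + 2L
      } else {
        hi <- row$end - 3L * (idx - 1L); lo <- hi - 2L
      }
      if (any(others$start <= hi & others$end >= lo)) next
      codon <- seq_collapse(if (row$strand == "+") ch[lo:hi] else
                              seq_chars(revcomp(seq_collapse(ch[lo:hi]))))
      if (codon %in% code$stops || grepl("N", codon)) next
      cands[[length(cands) + 1L]] <-
        data.frame(gene = g, codon_index = idx, lo = lo, hi = hi,
                   strand = row$strand, codon = codon, stringsAsFactors = FALSE)
    }
  }
  if (!length(cands)) stop("no mutable codons in target genes", call. = FALSE)
  cand <- do.call(rbind, cands)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]  # random order, no reuse

  changes <- list()
  apply_changes <- function(n_wanted, type) {
    placed <- 0L
    while (placed < n_wanted && nrow(cand) > 0L) {
      row <- cand[1L, ]; cand <<- cand[-1L, , drop = FALSE]
      muts <- codon_mutations(row$codon, code)
      muts <- muts[muts$type == type, , drop = FALSE]
      if (nrow(muts) == 0L) next
      to <- muts$to[sample.int(nrow(muts), 1L)]
      ## verification at application time
      same_aa <- code$map[[row$codon]] == code$map[[to]]
      stopifnot(!(to %in% code$stops), same_aa == (type == "s"))
      pos_diff <- which(seq_chars(row$codon) != seq_chars(to))
      stopifnot(length(pos_diff) == 1L)
      new_chars <- seq_chars(to)
      written <- if (row$strand == "+") new_chars else seq_chars(revcomp(to))
      ch[row$lo:row$hi] <<- written
      gpos <- if (row$strand == "+") row$lo + pos_diff - 1L else row$hi - pos_diff + 1L
      changes[[length(changes) + 1L]] <<-
        data.frame(gene = row$gene, codon_index = row$codon_index,
                   from_codon = row$codon, to_codon = to, type = type,
                   genome_pos = gpos, stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
    if (placed < n_wanted) {
      stop(sprintf("cannot place %d %ssynonymous substitutions (placed %d)",
                   n_wanted, ifelse(type == "s", "", "non"), placed), call. = FALSE)
    }
  }
  apply_changes(spec$n_syn, "s")
  apply_changes(spec$n_nonsyn, "n")

  rec_b <- mitogenome_record(f, sequence = seq_collapse(ch),
                             accession = paste0(record$accession, "-div"),
                             species = record$species)
  truth <- if (length(changes)) do.call(rbind, changes) else
    data.frame(gene = character(0), codon_index = integer(0),
               from_codon = character(0), to_codon = character(0),
               type = character(0), genome_pos = integer(0))
  list(record = rec_b, truth = truth)
}
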