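## Gene-junction arithmetic on the circular genome: overlaps, intergenic
## spacers, strand tallies, per-class length totals.

#' Junction-by-junction gap ledger
#'
#' One junction per consecutive feature pair in genomic (start) order, plus
#' the wrap-around junction from the last feature back to the first. The
#' signed gap is `start(downstream) - end(upstream) - 1`; for the wrapping
#' junction the downstream start is shifted by the genome length. Negative
#' gaps are overlaps, positive gaps intergenic spacers, zero means abutting.
#'
#' @param record A `mitogenome_record` with at least 2 features.
#' @return `data.frame` with columns `upstream_gene`, `downstream_gene`,
#'   `gap`, `wraps_origin`.
#' @export
#' @examples
#' t1 <- system.file("extdata", "tupaia_nicobarica_MW751815.tsv", package = "mitoarch")
#' j <- junction_ledger(read_gene_table(t1))
#' j[j$gap < -40, ]  # the atp8/atp6 overlap
junction_ledger <- function(record) {
  stopifnot(inherits(record, "mitogenome_record"))
  f <- record$features
  if (nrow(f) < 2L) stop("need at least 2 features for a junction ledger", call. = FALSE)
  if (is.unsorted(f$start)) stop("internal error: features not sorted by start", call. = FALSE)
  L <- genome_length(record)
  n <- nrow(f)
  up <- seq_len(n)
  down <- c(seq_len(n)[-1L], 1L)
  start_down <- f$start[down]
  start_down[n] <- start_down[n] + L  # wrap-around junction
  data.frame(upstream_gene = f$gene[up],
             downstream_gene = f$gene[down],
             gap = as.integer(start_down - f$end[up] - 1L),
             wraps_origin = c(rep(FALSE, n - 1L), TRUE),
             stringsAsFactors = FALSE)
}

#' Architecture report: overlap/spacer/strand/length tallies
#'
#' Summarises the junction ledger and the feature table: number and total
#' length of overlapping regions and intergenic spacers (gap-0 junctions
#' count as neither), the longest of each with the gene pair involved, the
#' plus/minus strand tally (features without a strand, i.e. the control
#' region, are excluded), and total bp per gene class.
#'
#' @param record A `mitogenome_record`.
#' @return Object of class `architecture_report`.
#' @export
architecture_report <- function(record) {
  stopifnot(inherits(record, "mitogenome_record"))
  f <- record$features
  j <- if (nrow(f) >= 2L) junction_ledger(record) else
    data.frame(upstream_gene = character(0), downstream_gene = character(0),
               gap = integer(0), wraps_origin = logical(0))
  ov <- j[j$gap < 0L, , drop = FALSE]
  sp <- j[j$gap > 0L, , drop = FALSE]
  pair_label <- function(row) paste0(row$upstream_gene, "-", row$downstream_gene)
  longest_of <- function(d, decreasing) {
    if (nrow(d) == 0L) return(list(pair = NA_character_, bp = 0L))
    i <- which.max(abs(d$gap))
    list(pair = pair_label(d[i, ]), bp = abs(d$gap[i]))
  }
  class_totals <- tapply(f$size, factor(f$gene_class, levels = GENE_CLASSES), sum)
  class_totals[is.na(class_totals)] <- 0L
  stranded <- f[!is.na(f$strand), , drop = FALSE]
  structure(list(
    junctions = j,
    n_overlaps = nrow(ov),
    total_overlap_bp = sum(abs(ov$gap)),
    longest_overlap = longest_of(ov),
    n_spacers = nrow(sp),
    total_spacer_bp = sum(sp$gap),
    longest_spacer = longest_of(sp),
    n_plus_strand = sum(stranded$strand == "+"),
    n_minus_strand = sum(stranded$strand == "-"),
    class_totals = as.list(class_totals),
    genome_length = genome_length(record)
  ), class = "architecture_report")
}

#' @export
print.architecture_report <- function(x, ...) {
  cat(sprintf("<architecture_report> genome %d bp; %d genes + strand, %d - strand\n",
              x$genome_length, x$n_plus_strand, x$n_minus_strand))
  cat(sprintf("  overlaps: %d (%d bp, longest %s %d bp)\n",
              x$n_overlaps, x$total_overlap_bp, x$longest_overlap$pair, x$longest_overlap$bp))
  cat(sprintf("  spacers : %d (%d bp, longest %s %d bp)\n",
              x$n_spacers, x$total_spacer_bp, x$longest_spacer$pair, x$longest_spacer$bp))
  ct <- unlist(x$class_totals)
  cat("  class bp:", paste(sprintf("%s=%d", names(ct), ct), collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of the genome covered by protein-coding genes
#'
#' `100 * sum(PCG sizes) / genome_length`. Overlapping PCG bases are counted
#' once per gene (concatenation semantics), matching how total coding length
#' is conventionally tabulated for mitogenomes. Full precision is returned;
#' round only for display.
#'
#' @param record A `mitogenome_record` with at least one PCG.
#' @return Percentage (numeric scalar).
#' @export
pcg_fraction <- function(record) {
  stopifnot(inherits(record, "mitogenome_record"))
  f <- record$features
  pcg <- f[f$gene_class == "PCG", , drop = FALSE]
  if (nrow(pcg) == 0L) stop("record has no protein-coding genes", call. = FALSE)
  L <- genome_length(record)
  if (L == 0L) stop("genome length is zero", call. = FALSE)
  100 * sum(pcg$size) / L
}
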