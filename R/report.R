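## Orchestration over one or more genomes: paper-style tables, gene-order
## comparison, cross-genome ranges, optional Ka/Ks matrix.

#' Are two or more gene orders identical?
#'
#' Compares the normalized gene-name sequences (genomic order,
#' strand-sensitive) of all records against the first. Names are normalized
#' through the package's synonym map (e.g. `COI`/`COX1`/`cox1`,
#' `D-loop`/`CR`) before comparison; unknown names pass through lowercased.
#'
#' @param records List of `mitogenome_record`s, length at least 2.
#' @return List: `identical` (flag), `first_divergence` (`NA` or list with
#'   `pair`, `index`, `genes`).
#' @export
gene_order_identical <- function(records) {
  if (length(records) < 2L) stop("need at least 2 records", call. = FALSE)
  key <- function(rec) {
    f <- rec$features
    paste0(vapply(f$gene, normalize_gene_name, character(1)),
           ifelse(is.na(f$strand), "", f$strand))
  }
  ref <- key(records[[1L]])
  for (i in 2L:length(records)) {
    cur <- key(records[[i]])
    n <- min(length(ref), length(cur))
    mismatch <- which(ref[seq_len(n)] != cur[seq_len(n)])
    if (length(mismatch) || length(ref) != length(cur)) {
      idx <- if (length(mismatch)) mismatch[1L] else n + 1L
      return(list(identical = FALSE,
                  first_divergence = list(pair = c(1L, i), index = idx,
                                          genes = c(ref[idx][1L], cur[idx][1L]))))
    }
  }
  list(identical = TRUE, first_divergence = NA)
}

#' Run the full comparative pipeline
#'
#' For each genome: architecture report, composition profiles (when a
#' sequence is present), start/stop codon table and RSCU (sequence + PCGs
#' present). Across genomes: gene-order identity, per-class length ranges
#' (computed only over genomes possessing the class), and a per-gene Ka/Ks
#' table for every genome pair when requested. Outputs are deterministic
#' given the inputs.
#'
#' @param genomes Named list; each element is either a `mitogenome_record`
#'   or a list with `table` (gene-table TSV path) and optional `fasta`.
#' @param out_dir Optional directory; when given, per-genome TSVs
#'   (`<name>_junctions.tsv`, `<name>_composition.tsv`, `<name>_rscu.tsv`)
#'   and a `summary.json` are written.
#' @param kaks_pairs Compute per-gene Ka/Ks for all genome pairs (requires
#'   sequences and equal codon counts per gene).
#' @param code A [codon_table()].
#' @return Object of class `comparative_report`.
#' @export
run_pipeline <- function(genomes, out_dir = NULL, kaks_pairs = FALSE,
                         code = codon_table()) {
  if (length(genomes) < 1L) stop("need at least one genome", call. = FALSE)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    names(genomes) <- paste0("genome", seq_along(genomes))
  }
  records <- lapply(names(genomes), function(nm) {
    g <- genomes[[nm]]
    if (inherits(g, "mitogenome_record")) return(g)
    tryCatch(read_gene_table(g$table, fasta = g$fasta, accession = nm),
             error = function(e) stop(sprintf("genome '%s': %s", nm, conditionMessage(e)),
                                      call. = FALSE))
  })
  names(records) <- names(genomes)

  per_genome <- lapply(names(records), function(nm) {
    rec <- records[[nm]]
    out <- list(architecture = architecture_report(rec))
    if (!is.null(rec$sequence)) {
      out$composition <- region_profiles(rec)
      if (any(rec$features$gene_class == "PCG")) {
        out$start_stop <- tryCatch(start_stop_table(rec, code), error = function(e) NULL)
        out$rscu <- tryCatch(rscu(codon_counts(rec, code = code), code),
                             error = function(e) NULL)
      }
    }
    out
  })
  names(per_genome) <- names(records)

  class_ranges <- NULL
  ct <- do.call(rbind, lapply(per_genome, function(x) unlist(x$architecture$class_totals)))
  if (!is.null(ct)) {
    class_ranges <- data.frame(gene_class = colnames(ct),
                               min_bp = apply(ct, 2L, function(v) min(v[v > 0])),
                               max_bp = apply(ct, 2L, function(v) max(v[v > 0])),
                               stringsAsFactors = FALSE)
    class_ranges <- class_ranges[apply(ct, 2L, function(v) any(v > 0)), ]
    rownames(class_ranges) <- NULL
  }

  order_check <- if (length(records) >= 2L) gene_order_identical(records) else
    list(identical = TRUE, first_divergence = NA)

  kaks_out <- NULL
  if (isTRUE(kaks_pairs) && length(records) >= 2L) {
    combos <- utils::combn(names(records), 2L, simplify = FALSE)
    kaks_out <- do.call(rbind, lapply(combos, function(pr) {
      tab <- kaks_table(records[[pr[1L]]], records[[pr[2L]]], code = code)
      if (is.null(tab)) return(NULL)
      cbind(data.frame(genome_a = pr[1L], genome_b = pr[2L],
                       stringsAsFactors = FALSE), tab)
    }))
  }

  rep <- structure(list(records = records, per_genome = per_genome,
                        class_ranges = class_ranges, gene_order = order_check,
                        kaks = kaks_out),
                   class = "comparative_report")
  if (!is.null(out_dir)) write_report_files(rep, out_dir)
  rep
}

write_report_files <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  for (nm in names(rep$per_genome)) {
    pg <- rep$per_genome[[nm]]
    wt(pg$architecture$junctions, file.path(out_dir, paste0(nm, "_junctions.tsv")))
    if (!is.null(pg$composition)) {
      wt(pg$composition, file.path(out_dir, paste0(nm, "_composition.tsv")))
    }
    if (!is.null(pg$rscu)) wt(pg$rscu, file.path(out_dir, paste0(nm, "_rscu.tsv")))
  }
  if (!is.null(rep$kaks)) wt(rep$kaks, file.path(out_dir, "kaks.tsv"))
  summary <- list(
    genomes = lapply(rep$per_genome, function(pg) {
      a <- pg$architecture
      list(genome_length = a$genome_length, n_overlaps = a$n_overlaps,
           total_overlap_bp = a$total_overlap_bp, n_spacers = a$n_spacers,
           total_spacer_bp = a$total_spacer_bp,
           n_minus_strand = a$n_minus_strand, class_totals = a$class_totals)
    }),
    gene_order_identical = rep$gene_order$identical)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.comparative_report <- function(x, ...) {
  cat(sprintf("<comparative_report> %d genome(s); gene order %s\n",
              length(x$records),
              if (x$gene_order$identical) "identical" else "DIVERGENT"))
  for (nm in names(x$per_genome)) {
    a <- x$per_genome[[nm]]$architecture
    cat(sprintf("  %s: %d bp, %d overlaps (%d bp), %d spacers (%d bp)\n", nm,
                a$genome_length, a$n_overlaps, a$total_overlap_bp,
                a$n_spacers, a$total_spacer_bp))
  }
  invisible(x)
}
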