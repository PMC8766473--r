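## Annotated-mitogenome IO: GenBank flat files, FASTA + gene-table TSV, and
## the canonical in-memory record.

GENE_CLASSES <- c("PCG", "tRNA", "rRNA", "control_region")

GENE_TABLE_COLS <- c("gene", "strand", "start", "end", "size",
                     "anticodon", "start_codon", "stop_codon")

## Canonical gene-name normalization (COX1/COI/cox1 -> cox1; D-loop -> CR ...).
## Unknown names pass through lowercased (CR stays upper).
normalize_gene_name <- function(name) {
  key <- tolower(gsub("[ _-]", "", name))
  map <- c(coi = "cox1", coii = "cox2", coiii = "cox3",
           co1 = "cox1", co2 = "cox2", co3 = "cox3",
           cytb = "cob", dloop = "CR", cr = "CR",
           "12srrna" = "rrnS", "16srrna" = "rrnL",
           rrns = "rrnS", rrnl = "rrnL",
           nd1 = "nad1", nd2 = "nad2", nd3 = "nad3", nd4 = "nad4",
           nd4l = "nad4l", nd5 = "nad5", nad6 = "nad6", nd6 = "nad6")
  if (key %in% names(map)) return(unname(map[key]))
  if (grepl("^(trn|rrn)", key)) {
    ## keep the compartment suffix case (trnS1, rrnS, rrnL)
    pre <- substr(key, 1, 3)
    suf <- substr(name, 4, nchar(name))
    return(paste0(pre, suf))
  }
  tolower(name)
}

classify_gene_name <- function(name) {
  ifelse(grepl("^trn", name), "tRNA",
  ifelse(grepl("^rrn", name), "rRNA",
  ifelse(name %in% c("CR", "D-loop", "cr", "dloop"), "control_region", "PCG")))
}

#' Construct one annotated gene feature
#'
#' One row of the canonical gene table: a named gene with 1-based inclusive
#' coordinates, strand, and codon metadata. Absent values are `NA`.
#'
#' @param gene Gene symbol (e.g. `"atp8"`, `"trnF"`, `"rrnS"`, `"CR"`).
#' @param strand `"+"`, `"-"`, or `NA` (control region carries no strand).
#' @param start,end 1-based inclusive coordinates, `start <= end`
#'   (origin-spanning features are not supported).
#' @param size Length in bp; derived as `end - start + 1` when `NULL`.
#' @param anticodon 3-mer for tRNAs, else `NA`.
#' @param start_codon 3-mer for protein-coding genes, else `NA`.
#' @param stop_codon Stop token; incomplete stops keep their completed form in
#'   parentheses, e.g. `"T(AA)"`.
#' @param gene_class One of `PCG`, `tRNA`, `rRNA`, `control_region`; inferred
#'   from the gene name when `NULL`.
#' @return A one-row `data.frame` with the canonical columns.
#' @export
#' @examples
#' gene_feature("atp8", "+", 7753, 7956, start_codon = "ATG", stop_codon = "TAA")
gene_feature <- function(gene, strand, start, end, size = NULL,
                         anticodon = NA_character_, start_codon = NA_character_,
                         stop_codon = NA_character_, gene_class = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop(sprintf("gene '%s': invalid coordinates %s..%s (origin-spanning features unsupported)",
                 gene, start, end), call. = FALSE)
  }
  if (is.null(size) || is.na(size)) size <- end - start + 1L
  size <- as.integer(size)
  if (size != end - start + 1L) {
    stop(sprintf("gene '%s': size %d contradicts coordinates %d..%d (expect %d)",
                 gene, size, start, end, end - start + 1L), call. = FALSE)
  }
  if (is.null(gene_class)) gene_class <- classify_gene_name(gene)
  stopifnot(gene_class %in% GENE_CLASSES)
  if (!is.na(strand) && !strand %in% c("+", "-")) {
    stop(sprintf("gene '%s': strand must be '+', '-' or NA", gene), call. = FALSE)
  }
  data.frame(gene = gene, gene_class = gene_class, strand = strand,
             start = start, end = end, size = size,
             anticodon = anticodon, start_codon = start_codon,
             stop_codon = stop_codon, stringsAsFactors = FALSE)
}

#' Is a stop-codon token incomplete?
#'
#' Incomplete stops (completed to TAA by polyadenylation) are written as the
#' residual nucleotides followed by the completion in parentheses, e.g.
#' `"T(AA)"` or `"TA(A)"`; bare 1- or 2-mers are also flagged incomplete.
#'
#' @param token Stop-codon token(s).
#' @return Logical vector.
#' @export
is_incomplete_stop <- function(token) {
  !is.na(token) & (grepl("^[ACGT]{1,2}\\([ACGT]{1,2}\\)$", token) |
                     nchar(token) %in% c(1L, 2L))
}

sort_features <- function(features) {
  features[order(features$start, -features$end), , drop = FALSE]
}

#' Assemble a mitogenome record
#'
#' The package's canonical container: an optional circular DNA sequence plus
#' an ordered feature table (sorted by start, ties by end descending) and
#' accession/species labels.
#'
#' @param features `data.frame` of features as produced by [gene_feature()]
#'   (rows may be given in any order).
#' @param sequence Optional DNA string over `A,C,G,T,N`.
#' @param accession,species Labels.
#' @return An object of class `mitogenome_record`.
#' @export
mitogenome_record <- function(features, sequence = NULL,
                              accession = NA_character_, species = NA_character_) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0L) stop("empty record: no features", call. = FALSE)
  missing_cols <- setdiff(c("gene", "gene_class", "strand", "start", "end", "size"),
                          names(features))
  if (length(missing_cols)) stop("features missing columns: ",
                                 paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- features$size != features$end - features$start + 1L
  if (any(bad)) {
    stop("size contradicts coordinates for rows: ",
         paste(features$gene[bad], collapse = ", "), call. = FALSE)
  }
  pcg <- features$gene_class == "PCG"
  if (any(pcg & is.na(features$start_codon))) {
    stop("PCG features must carry a start codon: ",
         paste(features$gene[pcg & is.na(features$start_codon)], collapse = ", "),
         call. = FALSE)
  }
  features <- sort_features(features)
  rownames(features) <- NULL
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    validate_dna(sequence)
    if (max(features$end) > nchar(sequence)) {
      stop(sprintf("sequence length %d shorter than max feature end %d",
                   nchar(sequence), max(features$end)), call. = FALSE)
    }
  }
  structure(list(accession = accession, species = species,
                 sequence = sequence, features = features),
            class = "mitogenome_record")
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat(sprintf("<mitogenome_record> %s%s: %d features%s\n",
              ifelse(is.na(x$accession), "(no accession)", x$accession),
              ifelse(is.na(x$species), "", paste0(" [", x$species, "]")),
              nrow(x$features),
              if (is.null(x$sequence)) "" else sprintf(", %d bp", nchar(x$sequence))))
  print(utils::head(x$features, 5L))
  if (nrow(x$features) > 5L) cat("  ...\n")
  invisible(x)
}

#' Genome length of a record
#'
#' Sequence length when a sequence is attached, otherwise the maximum feature
#' end (the record is assumed to tile the circle, as annotated mitogenomes do).
#'
#' @param record A `mitogenome_record`.
#' @return Integer length in bp.
#' @export
genome_length <- function(record) {
  if (!is.null(record$sequence)) nchar(record$sequence) else max(record$features$end)
}

#' Read a gene table (TSV) into a mitogenome record
#'
#' The TSV dialect is UTF-8, tab-separated, header
#' `gene strand start end size anticodon start_codon stop_codon`, with `"."`
#' for absent values. The `size` column is optional and derived from the
#' coordinates when missing; a size contradicting its coordinates is a
#' validation error naming the offending rows.
#'
#' @param tsv Path to the gene table.
#' @param fasta Optional FASTA path; the (single) sequence is attached and
#'   length-checked against the feature coordinates.
#' @param accession,species Labels.
#' @return A `mitogenome_record`.
#' @export
#' @examples
#' t1 <- system.file("extdata", "tupaia_nicobarica_MW751815.tsv", package = "mitoarch")
#' rec <- read_gene_table(t1)
#' table(rec$features$gene_class)
read_gene_table <- function(tsv, fasta = NULL,
                            accession = NA_character_, species = NA_character_) {
  df <- read.delim(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L) stop("empty gene table: ", tsv, call. = FALSE)
  need <- c("gene", "strand", "start", "end")
  if (!all(need %in% names(df))) {
    stop("gene table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  dot_na <- function(x) ifelse(is.na(x) | x %in% c(".", ""), NA_character_, x)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    size <- if ("size" %in% names(df)) suppressWarnings(as.integer(df$size[i])) else NULL
    gene_feature(gene = df$gene[i],
                 strand = dot_na(df$strand[i]),
                 start = as.integer(df$start[i]), end = as.integer(df$end[i]),
                 size = size,
                 anticodon = dot_na(if ("anticodon" %in% names(df)) df$anticodon[i] else NA),
                 start_codon = dot_na(if ("start_codon" %in% names(df)) df$start_codon[i] else NA),
                 stop_codon = dot_na(if ("stop_codon" %in% names(df)) df$stop_codon[i] else NA))
  })
  features <- do.call(rbind, rows)
  sequence <- NULL
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    if (length(seqs) != 1L) stop("expected exactly one FASTA sequence, got ",
                                 length(seqs), call. = FALSE)
    sequence <- unname(seqs[1L])
  }
  mitogenome_record(features, sequence = sequence,
                    accession = accession, species = species)
}

#' Write a record's features as a gene-table TSV
#'
#' Deterministic formatting: features sorted by start, `"."` for absent
#' values, fixed column order. `read_gene_table(write_gene_table(x))` is the
#' identity on features.
#'
#' @param record A `mitogenome_record`.
#' @param path Output path, or `NULL` to return the TSV text.
#' @return Invisibly the path, or the TSV text when `path` is `NULL`.
#' @export
write_gene_table <- function(record, path = NULL) {
  stopifnot(inherits(record, "mitogenome_record"))
  df <- record$features[, GENE_TABLE_COLS]
  for (col in GENE_TABLE_COLS) {
    df[[col]] <- ifelse(is.na(df[[col]]), ".", as.character(df[[col]]))
  }
  lines <- c(paste(GENE_TABLE_COLS, collapse = "\t"),
             apply(df, 1L, paste, collapse = "\t"))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(path)
}

## --- GenBank flat file ------------------------------------------------------

genbank_feature_class <- function(key) {
  switch(key,
         CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
         D_loop = "control_region", "D-loop" = "control_region",
         misc_feature = "control_region",
         NA_character_)
}

parse_genbank_location <- function(loc, line_no) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|complement", loc)) {
    stop(sprintf("unsupported feature location '%s' (line %d): origin-spanning/compound locations are not supported",
                 loc, line_no), call. = FALSE)
  }
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1L]]
  if (length(m) != 3L) {
    if (grepl("^[0-9]+$", loc)) m <- c(loc, loc, loc)  # single-base feature
    else stop(sprintf("malformed location '%s' at line %d", loc, line_no), call. = FALSE)
  }
  list(start = as.integer(m[2L]), end = as.integer(m[3L]), strand = strand)
}

#' Read a GenBank flat file into a mitogenome record
#'
#' Parses `LOCUS`, the `FEATURES` table and `ORIGIN`. `CDS`, `tRNA`, `rRNA`
#' and `D-loop`/`misc_feature` keys are mapped to the four gene classes (the
#' control region is named `"CR"`); gene classes come from the feature key,
#' not the gene name. `complement(a..b)` locations get strand `-`.
#' Compound (`join`) and origin-spanning locations raise an explicit
#' unsupported-feature error; other malformed lines raise a parse error
#' naming the line.
#'
#' @param path GenBank flat file.
#' @return A `mitogenome_record` (sequence attached when `ORIGIN` present).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1L])) {
    stop("malformed GenBank file (line 1): missing LOCUS", call. = FALSE)
  }
  accession <- NA_character_; species <- NA_character_
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) accession <- strsplit(trimws(sub("^ACCESSION", "", acc_line[1L])), "\\s+")[[1L]][1L]
  org_line <- grep("^\\s{2}ORGANISM", lines, value = TRUE)
  if (length(org_line)) species <- trimws(sub("^\\s+ORGANISM", "", org_line[1L]))

  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) stop("malformed GenBank file: missing FEATURES", call. = FALSE)
  origin_at <- grep("^ORIGIN", lines)
  feat_end <- if (length(origin_at)) origin_at[1L] - 1L else length(lines)
  feats <- list()
  i <- feat_start[1L] + 1L
  while (i <= feat_end) {
    line <- lines[i]
    m <- regmatches(line, regexec("^\\s{5}(\\S+)\\s+(\\S+)\\s*$", line))[[1L]]
    if (length(m) == 3L && !grepl("^\\s{21}", line)) {
      key <- m[2L]; loc_text <- m[3L]; loc_line <- i
      quals <- character(0)
      j <- i + 1L
      while (j <= feat_end && grepl("^\\s{21}", lines[j])) {
        quals <- c(quals, trimws(lines[j])); j <- j + 1L
      }
      cls <- genbank_feature_class(key)
      if (!is.na(cls)) {
        loc <- parse_genbank_location(loc_text, loc_line)
        getq <- function(q) {
          hit <- grep(paste0("^/", q, "="), quals, value = TRUE)
          if (!length(hit)) return(NA_character_)
          gsub('"', "", sub(paste0("^/", q, "="), "", hit[1L]))
        }
        name <- getq("gene")
        if (is.na(name)) name <- getq("product")
        if (cls == "control_region") name <- "CR"
        if (is.na(name)) name <- key
        name <- normalize_gene_name(name)
        start_codon <- NA_character_
        if (cls == "PCG") start_codon <- "NNN"  # filled from sequence if present
        feats[[length(feats) + 1L]] <-
          gene_feature(name,
                       strand = if (cls == "control_region") NA_character_ else loc$strand,
                       start = loc$start, end = loc$end,
                       start_codon = start_codon, gene_class = cls)
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(feats)) stop("GenBank file has no usable features", call. = FALSE)
  features <- do.call(rbind, feats)

  sequence <- NULL
  if (length(origin_at)) {
    seq_lines <- lines[(origin_at[1L] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (nzchar(sequence)) validate_dna(sequence) else sequence <- NULL
  }
  ## fill start/stop codons for CDS features from the sequence
  if (!is.null(sequence)) {
    for (r in which(features$gene_class == "PCG")) {
      cds <- substr(sequence, features$start[r], features$end[r])
      if (features$strand[r] == "-") cds <- revcomp(cds)
      features$start_codon[r] <- substr(cds, 1L, 3L)
      rem <- nchar(cds) %% 3L
      features$stop_codon[r] <- if (rem == 0L) substr(cds, nchar(cds) - 2L, nchar(cds))
                                else incomplete_stop_token(substr(cds, nchar(cds) - rem + 1L, nchar(cds)))
    }
  } else {
    features$start_codon[features$gene_class == "PCG"] <- NA_character_
    ## records without sequence keep PCGs valid by marking starts unknown
    features$start_codon[features$gene_class == "PCG"] <- "NNN"
  }
  mitogenome_record(features, sequence = sequence,
                    accession = accession, species = species)
}

incomplete_stop_token <- function(residual) {
  paste0(residual, "(", substr("TAA", nchar(residual) + 1L, 3L), ")")
}
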