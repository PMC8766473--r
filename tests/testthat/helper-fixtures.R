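## Shared fixtures: the packaged 38-row gene table, tiny handcrafted GenBank
## text, and random-sequence helpers. Everything is built in code.

fixture_record <- function(...) {
  read_gene_table(default_gene_table_path(), ...)
}

## the Intergenic Nucleotides column as printed in the reference table
## (trnF..trnP rows; the CR row carries no downstream spacer entry)
PRINTED_INTERGENIC <- c(
  -1, 4, 0, 0, 2, -2, -3, -1, 0, -2, 4, 1, 33, 0, 1, -5, 4, 0, 1, 2,
  -43, -1, -1, 9, -10, 1, -7, 0, 0, -1, -9, 2, 0, 3, -1, 1, 0)

tiny_genbank <- function(path,
                         features = c(
                           "     CDS             1..9",
                           "                     /gene=\"nad1\"",
                           "     tRNA            complement(3754..3824)",
                           "                     /gene=\"trnQ\"",
                           "     rRNA            12..20",
                           "                     /gene=\"rrnS\"",
                           "     D-loop          30..40"),
                         sequence = NULL, length_bp = 4000) {
  lines <- c(
    sprintf("LOCUS       TESTREC %d bp    DNA     circular VRT", length_bp),
    "DEFINITION  handcrafted test record.",
    "ACCESSION   TEST0001",
    "  ORGANISM  Testus testus",
    "FEATURES             Location/Qualifiers",
    features)
  if (!is.null(sequence)) {
    lines <- c(lines, "ORIGIN",
               paste0("        1 ", tolower(sequence)), "//")
  } else {
    lines <- c(lines, "//")
  }
  writeLines(lines, path)
  path
}

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste0(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

sense_codons_of <- function(code) setdiff(names(code$map), code$stops)

random_sense_codons <- function(n, code) {
  sample(sense_codons_of(code), n, replace = TRUE)
}

## a minimal record wrapping a raw CDS as a single plus-strand PCG
cds_record <- function(cds, pad = "") {
  seqs <- paste0(cds, pad)
  feats <- rbind(
    gene_feature("g1", "+", 1, nchar(cds), start_codon = substr(cds, 1, 3),
                 stop_codon = substr(cds, nchar(cds) - 2, nchar(cds))),
    gene_feature("CR", NA, nchar(cds) + 1, nchar(seqs) + 10))
  mitogenome_record(feats, sequence = paste0(seqs, strrep("A", 10)))
}
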