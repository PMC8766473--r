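test_that("packaged reference table parses to the expected class census", {
  rec <- fixture_record(accession = "MW751815", species = "Tupaia nicobarica")
  cls <- table(rec$features$gene_class)
  expect_equal(unname(cls[["PCG"]]), 13)
  expect_equal(unname(cls[["tRNA"]]), 22)
  expect_equal(unname(cls[["rRNA"]]), 2)
  expect_equal(unname(cls[["control_region"]]), 1)
  expect_equal(max(rec$features$end), 17164)
  expect_equal(rec$features$size, rec$features$end - rec$features$start + 1L)
  ## minus-strand census: nad6 plus eight tRNAs
  minus <- rec$features[!is.na(rec$features$strand) & rec$features$strand == "-", ]
  expect_setequal(minus$gene,
                  c("trnQ", "trnA", "trnN", "trnC", "trnY", "trnS2", "nad6",
                    "trnE", "trnP"))
})

test_that("size column is derived when absent and validated when present", {
  df <- utils::read.delim(default_gene_table_path(), colClasses = "character")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[, setdiff(names(df), "size")], tmp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rec <- read_gene_table(tmp)
  expect_equal(rec$features$size[rec$features$gene == "atp8"], 204L)

  df_bad <- df
  df_bad$size[df_bad$gene == "atp8"] <- "999"
  utils::write.table(df_bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_table(tmp), "atp8")
})

test_that("degenerate gene tables are rejected", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tstrand\tstart\tend", tmp)
  expect_error(read_gene_table(tmp), "empty")
  writeLines(c("gene\tstrand\tstart\tend", "g1\t+\t50\t10"), tmp)
  expect_error(read_gene_table(tmp), "coordinates")
})

test_that("gene-table round trip is the identity on features", {
  rec <- fixture_record()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(rec, tmp)
  back <- read_gene_table(tmp)
  expect_identical(back$features, rec$features)
  ## text form: header + 38 data rows, deterministic
  txt <- write_gene_table(rec)
  expect_length(strsplit(txt, "\n")[[1]], 39L)
  expect_identical(write_gene_table(back), txt)
})

test_that("unsorted feature input comes back sorted by start", {
  rec <- fixture_record()
  shuffled <- rec$features[rev(seq_len(nrow(rec$features))), ]
  rec2 <- mitogenome_record(shuffled)
  expect_identical(rec2$features, rec$features)
  expect_false(is.unsorted(rec2$features$start))
})

test_that("GenBank parsing maps keys to classes and complement to minus strand", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  tiny_genbank(tmp)
  rec <- read_genbank(tmp)
  f <- rec$features
  expect_equal(rec$accession, "TEST0001")
  expect_equal(f$gene_class[f$gene == "nad1"], "PCG")
  expect_equal(f$size[f$gene == "nad1"], 9L)
  q <- f[f$gene == "trnQ", ]
  expect_equal(q$strand, "-")
  expect_equal(c(q$start, q$end), c(3754L, 3824L))
  expect_equal(f$gene[f$gene_class == "control_region"], "CR")
})

test_that("GenBank CDS codons are read from ORIGIN when present", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  tiny_genbank(tmp,
               features = c("     CDS             1..9",
                            "                     /gene=\"nad1\""),
               sequence = "atgaaataa", length_bp = 9)
  rec <- read_genbank(tmp)
  expect_equal(rec$sequence, "ATGAAATAA")
  expect_equal(rec$features$start_codon[1], "ATG")
  expect_equal(rec$features$stop_codon[1], "TAA")
})

test_that("malformed and origin-spanning GenBank inputs fail loudly", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines("not a genbank file", tmp)
  expect_error(read_genbank(tmp), "LOCUS")
  tiny_genbank(tmp, features = c("     CDS             join(15000..17164,1..20)",
                                 "                     /gene=\"wrap\""))
  expect_error(read_genbank(tmp), "origin-spanning|unsupported")
})

test_that("incomplete stop tokens are recognised and preserved verbatim", {
  expect_true(all(is_incomplete_stop(c("T(AA)", "TA(A)", "T", "TA"))))
  expect_false(any(is_incomplete_stop(c("TAA", "AGA", "AGG", NA))))
  rec <- fixture_record()
  expect_equal(rec$features$stop_codon[rec$features$gene == "nad4"], "T(AA)")
})

test_that("record invariants are enforced", {
  expect_error(mitogenome_record(data.frame()), "empty")
  pcg_no_start <- gene_feature("nadx", "+", 1, 9)
  pcg_no_start$start_codon <- NA_character_
  expect_error(mitogenome_record(pcg_no_start), "start codon")
  f <- gene_feature("trnX", "+", 1, 70, anticodon = "AAA")
  expect_error(mitogenome_record(f, sequence = "ACGT"), "shorter")
})
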