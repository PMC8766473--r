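test_that("the vertebrate mitochondrial code drives stops and families", {
  ct <- codon_table()
  expect_setequal(ct$stops, c("TAA", "TAG", "AGA", "AGG"))
  expect_equal(unname(ct$map["ATA"]), "M")
  expect_equal(unname(ct$map["TGA"]), "W")
  expect_setequal(ct$families$M, c("ATA", "ATG"))  # Met is 2-fold here
  expect_equal(length(ct$families$W), 2L)           # TGA + TGG
  expect_equal(sum(lengths(ct$families)), 60L)
  ## the standard code differs exactly where it should
  std <- codon_table("standard")
  expect_setequal(std$stops, c("TAA", "TAG", "TGA"))
})

test_that("a minimal CDS is decomposed into start, body, stop", {
  rec <- cds_record("ATGAAATAA")
  x <- extract_codons(rec, "g1")
  expect_equal(x$start_codon, "ATG")
  expect_equal(x$stop_codon, "TAA")
  expect_equal(x$codons, c("ATG", "AAA"))
  expect_false(x$incomplete_stop)
})

test_that("incomplete terminal codons become T(AA)-style tokens", {
  ## 1378 bp = 459 full codons + 1 nt, the nad4 layout
  g <- generate_genome(genome_spec(seed = 7))
  x <- extract_codons(g$record, "nad4")
  expect_equal(x$stop_codon, "T(AA)")
  expect_true(x$incomplete_stop)
  expect_length(x$codons, 459L)
  ## declared non-ATG start survives generation: nad2 starts ATC
  expect_equal(extract_codons(g$record, "nad2")$start_codon, "ATC")
})

test_that("minus-strand extraction equals the reverse-complement construction", {
  g <- generate_genome(genome_spec(seed = 12))
  f <- g$record$features
  row <- f[f$gene == "nad6", ]
  x <- extract_codons(g$record, "nad6")
  cds <- revcomp(substr(g$record$sequence, row$start, row$end))
  manual <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  expect_equal(x$codons, manual[-length(manual)])
  expect_equal(x$stop_codon, manual[length(manual)])
})

test_that("internal stop codons warn and are indexed", {
  rec <- cds_record("ATGTAAAAATAA")  # TAA at codon 2
  expect_warning(x <- extract_codons(rec, "g1"), "internal stop")
  expect_equal(x$internal_stops, 2L)
  expect_error(extract_codons(rec, "CR"), "not a protein-coding")
  short <- mitogenome_record(
    gene_feature("nad9", "+", 1, 4, start_codon = "ATG"),
    sequence = "ATGA")
  expect_error(extract_codons(short, "nad9"), "shorter than 6")
})

test_that("RSCU matches hand-computed family values", {
  r <- rscu(c(GCA = 3, GCC = 1))
  ala <- r[r$aa == "A", ]
  expect_equal(ala$rscu[match(c("GCA", "GCC", "GCG", "GCT"), ala$codon)],
               c(3, 1, 0, 0))
  expect_equal(sum(ala$rscu), unique(ala$degeneracy))

  r <- rscu(c(TTT = 5, TTC = 5))
  phe <- r[r$aa == "F", ]
  expect_equal(sort(phe$rscu), c(1, 1))

  ## uniform usage in every family -> all RSCU 1
  ct <- codon_table()
  uniform <- stats::setNames(rep(2L, 60), sense_codons_of(ct))
  r <- rscu(uniform, ct)
  expect_true(all(r$rscu == 1))

  ## zero-total family undefined, not zero
  r <- rscu(c(TTT = 4))
  expect_true(all(is.na(r$rscu[r$aa == "A"])))
  expect_error(rscu(c(TTT = 0)), "no codons")
  expect_error(rscu(c(XXX = 1)), "unknown codons")
})

test_that("RSCU sums to family degeneracy on random count tables", {
  ct <- codon_table()
  set.seed(21)
  for (i in 1:20) {
    counts <- stats::setNames(rpois(60, lambda = sample(1:20, 1)),
                              sense_codons_of(ct))
    r <- rscu(counts, ct)
    for (aa in unique(r$aa)) {
      fam <- r[r$aa == aa, ]
      if (all(is.na(fam$rscu))) next
      expect_equal(sum(fam$rscu), fam$degeneracy[1])
      expect_true(all(fam$rscu >= 0))
    }
  }
})

test_that("amino-acid abundance is a normalized frequency vector", {
  a <- aa_abundance(c(TTA = 2, CTA = 3))      # all Leu
  expect_equal(unname(a[["L"]]), 1)
  a <- aa_abundance(c(GCA = 3, CCA = 1))      # 3 Ala + 1 Pro
  expect_equal(unname(a[["A"]]), 0.75)
  expect_equal(unname(a[["P"]]), 0.25)
  expect_equal(sum(a), 1)
})

test_that("generator ground-truth codon counts reproduce the genome RSCU", {
  g <- generate_genome(genome_spec(seed = 31))
  counts <- suppressWarnings(codon_counts(g$record))
  truth <- g$truth$codon_counts
  expect_equal(counts[sort(names(counts))], truth[sort(names(truth))])
  expect_equal(rscu(counts), rscu(truth))
  expect_equal(aa_abundance(counts), aa_abundance(truth))
})
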