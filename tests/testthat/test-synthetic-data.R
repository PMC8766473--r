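test_that("default layout reproduces the packaged gene table", {
  g <- generate_genome(genome_spec(seed = 7))
  ref <- fixture_record()
  expect_identical(g$record$features, ref$features)
  expect_equal(nchar(g$record$sequence), 17164L)
})

test_that("generation is deterministic in the seed", {
  a <- generate_genome(genome_spec(seed = 7))
  b <- generate_genome(genome_spec(seed = 7))
  c <- generate_genome(genome_spec(seed = 8))
  expect_identical(a$record$sequence, b$record$sequence)
  expect_false(identical(a$record$sequence, c$record$sequence))
  expect_identical(a$truth$codon_counts, b$truth$codon_counts)
})

test_that("generated genomes satisfy the architecture conservation identity", {
  for (seed in c(1, 2, 3)) {
    g <- generate_genome(genome_spec(seed = seed))
    a <- architecture_report(g$record)
    expect_equal(sum(unlist(a$class_totals)) + a$total_spacer_bp -
                   a$total_overlap_bp, a$genome_length)
  }
})

test_that("declared codon metadata survives generation except adjusted tails", {
  g <- generate_genome(genome_spec(seed = 7))
  ss <- suppressWarnings(start_stop_table(g$record))
  declared <- fixture_record()$features
  declared <- declared[declared$gene_class == "PCG", ]
  m <- match(ss$gene, declared$gene)
  expect_equal(ss$start_codon, declared$start_codon[m])
  intact <- !(ss$gene %in% g$truth$adjusted_tail)
  expect_equal(ss$stop_codon[intact], declared$stop_codon[m][intact])
  ## downstream-frame overwrites are exactly the overlapped PCG tails
  expect_setequal(g$truth$adjusted_tail, c("atp8", "atp6", "nad4l"))
})

test_that("base composition of a large generated region converges (chi-square)", {
  probs <- c(A = 0.35, C = 0.22, G = 0.17, T = 0.26)
  f <- gene_feature("rrnS", "+", 1, 12000)
  spec <- genome_spec(seed = 13, gene_table = f,
                      base_probs = list(rRNA = probs))
  g <- generate_genome(spec)
  counts <- table(factor(seq_chars(g$record$sequence), levels = DNA_BASES))
  test <- stats::chisq.test(counts, p = probs[DNA_BASES])
  expect_gt(test$p.value, 0.001)
})

test_that("planted repeat location and content are in the ledger", {
  g <- generate_genome(genome_spec(seed = 7))
  tr <- g$truth$planted_repeat
  expect_equal(tr$motif, "CGTACA")
  expect_equal(tr$period, 6L)
  expect_equal(tr$copies, 362 / 6)
  arr <- substr(g$record$sequence, tr$start, tr$end)
  expect_equal(substr(arr, 1, 6), "CGTACA")
  expect_equal(nchar(arr), 362L)
})

test_that("infeasible layouts are rejected naming the genes", {
  f <- rbind(
    gene_feature("nad1", "+", 1, 30, start_codon = "ATG", stop_codon = "TAA"),
    gene_feature("nad2", "+", 2, 40, start_codon = "ATG", stop_codon = "TAA"))
  expect_error(generate_genome(genome_spec(seed = 1, gene_table = f)),
               "nad2.*start codon of nad1")
})

test_that("zero divergence returns an identical pair", {
  g <- generate_genome(genome_spec(seed = 5))
  div <- diverge_pair(g$record, divergence_spec(seed = 6, n_syn = 0, n_nonsyn = 0))
  expect_identical(div$record$sequence, g$record$sequence)
  expect_equal(nrow(div$truth), 0L)
})

test_that("divergence ground truth is verified against the genetic code", {
  g <- generate_genome(genome_spec(seed = 5))
  ct <- codon_table()
  div <- diverge_pair(g$record, divergence_spec(seed = 6, n_syn = 12, n_nonsyn = 3))
  expect_equal(sum(div$truth$type == "s"), 12L)
  expect_equal(sum(div$truth$type == "n"), 3L)
  expect_equal(anyDuplicated(div$truth[c("gene", "codon_index")]), 0L)
  for (i in seq_len(nrow(div$truth))) {
    ch <- div$truth[i, ]
    same_aa <- ct$map[[ch$from_codon]] == ct$map[[ch$to_codon]]
    expect_equal(same_aa, ch$type == "s")
    expect_false(ch$to_codon %in% ct$stops)
    ## exactly one nucleotide differs
    expect_equal(sum(seq_chars(ch$from_codon) != seq_chars(ch$to_codon)), 1L)
    ## the change is present in the output genome
    expect_equal(substr(g$record$sequence, ch$genome_pos, ch$genome_pos) ==
                   substr(div$record$sequence, ch$genome_pos, ch$genome_pos),
                 FALSE)
  }
})

test_that("impossible divergence requests fail loudly", {
  g <- generate_genome(genome_spec(seed = 5))
  expect_error(diverge_pair(g$record,
                            divergence_spec(seed = 6, n_syn = 10, genes = "trnF")),
               "not a PCG")
  expect_error(diverge_pair(g$record,
                            divergence_spec(seed = 6, n_syn = 100000)),
               "cannot place")
})

test_that("generated records round-trip through the gene table", {
  g <- generate_genome(genome_spec(seed = 9))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(g$record, tmp)
  expect_identical(read_gene_table(tmp)$features, g$record$features)
})
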