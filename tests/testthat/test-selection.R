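test_that("count_sites matches hand-enumerated codons", {
  ## TTT (Phe): only pos-3 T->C is synonymous
  expect_equal(count_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  ## TGA (Trp here): pos-1/pos-2 neighbours include stops (AGA, TAA), which
  ## drop from the denominators; pos-3 TGG is synonymous
  expect_equal(count_sites("TGA"), c(s = 1 / 3, n = 8 / 3))
  expect_error(count_sites("TAA"), "stop")
  expect_error(count_sites("XYZ"), "not a codon")
})

test_that("s + n = 3 for every sense codon, matching the enumeration oracle", {
  ct <- codon_table()
  for (codon in sense_codons_of(ct)) {
    got <- count_sites(codon, ct)
    expect_equal(unname(sum(got)), 3)
    expect_equal(got, oracle_count_sites(codon))
  }
})

test_that("count_differences classifies the canonical cases", {
  d <- count_differences("TTT", "TTC")
  expect_equal(c(d$sd, d$nd), c(1, 0))          # Phe -> Phe
  d <- count_differences("AAA", "AAA")
  expect_equal(c(d$sd, d$nd), c(0, 0))
  ## TTT vs GTC: both 2-step pathways give 1 synonymous + 1 nonsynonymous
  d <- count_differences("TTT", "GTC")
  expect_equal(c(d$sd, d$nd), c(1, 1))
  expect_error(count_differences("TAA", "TTT"), "stop")
})

test_that("pathway counting agrees with the exhaustive oracle", {
  ct <- codon_table()
  set.seed(33)
  sense <- sense_codons_of(ct)
  for (i in 1:300) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    d <- count_differences(a, b, ct)
    orc <- oracle_count_differences(a, b)
    if (is.null(orc)) {
      expect_true(d$blocked_fallback)
    } else {
      expect_equal(c(sd = d$sd, nd = d$nd), orc, tolerance = 1e-12)
      expect_false(d$blocked_fallback)
    }
  }
})

test_that("kaks is symmetric and conserves site totals", {
  ct <- codon_table()
  set.seed(44)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    a <- random_sense_codons(n, ct)
    b <- random_sense_codons(n, ct)
    r1 <- kaks(a, b, ct)
    r2 <- kaks(b, a, ct)
    expect_identical(r1[c("S_sites", "N_sites", "Sd", "Nd", "Ks", "Ka")],
                     r2[c("S_sites", "N_sites", "Sd", "Nd", "Ks", "Ka")])
    expect_equal(r1$S_sites + r1$N_sites, 3 * r1$n_codons_compared,
                 tolerance = 1e-9)
    expect_true(r1$Sd <= r1$S_sites + 1e-9 && r1$Nd <= r1$N_sites + 1e-9)
  }
})

test_that("identical sequences give zero distances and undefined ratio", {
  a <- rep("ATG", 10)
  r <- kaks(a, a)
  expect_equal(c(r$Ks, r$Ka), c(0, 0))
  expect_true(is.na(r$ratio))
})

test_that("two synonymous third-position changes give Ka 0 and JC-corrected Ks", {
  a <- rep("TTT", 100)
  b <- a; b[c(10, 60)] <- "TTC"
  r <- kaks(a, b)
  S <- 100 * (1 / 3)  # site oracle: every TTT contributes s = 1/3
  expect_equal(r$S_sites, S)
  expect_equal(r$Sd, 2)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ks, -0.75 * log(1 - 4 * (2 / S) / 3))
  expect_equal(r$Ka, 0)
  expect_equal(r$ratio, 0)
})

test_that("saturation flags undefined distances", {
  a <- rep("TTT", 30)
  b <- rep("TTC", 30)   # ps = 30 / 10 >= 3/4
  r <- kaks(a, b)
  expect_true(is.na(r$Ks))
  expect_true(is.na(r$ratio))
  expect_true("saturated" %in% r$flags)
})

test_that("degenerate inputs are rejected and gap codons dropped pairwise", {
  expect_error(kaks(rep("ATG", 3), rep("ATG", 4)), "length")
  expect_error(kaks(c("A-G"), c("ATG")), "zero comparable")
  r <- kaks(c("ATG", "A-G", "TTT"), c("ATG", "ATG", "TTT"))
  expect_equal(r$n_codons_compared, 2L)
})

test_that("generator divergence is recovered exactly before correction", {
  g <- generate_genome(genome_spec(seed = 51))
  div <- diverge_pair(g$record, divergence_spec(seed = 52, n_syn = 10,
                                                n_nonsyn = 0, genes = "nad5"))
  tab <- kaks_table(g$record, div$record, genes = "nad5")
  expect_equal(tab$Sd, 10)
  expect_equal(tab$Nd, 0)
  expect_equal(tab$Ka, 0)

  div2 <- diverge_pair(g$record, divergence_spec(seed = 53, n_syn = 20,
                                                 n_nonsyn = 2, genes = "nad5"))
  tab2 <- kaks_table(g$record, div2$record, genes = "nad5")
  expect_equal(tab2$Sd, 20)
  expect_equal(tab2$Nd, 2)
  expect_lt(tab2$ratio, 1)
})
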