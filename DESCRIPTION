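Package: mitoarch
Title: Comparative Architecture and Molecular Evolution of Annotated Mitogenomes
Version: 0.1.0
Authors@R: person("Mitoarch", "Developers", email = "mitoarch@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular mitochondrial
    genomes: gene-junction arithmetic (overlaps and intergenic spacers on the
    circle), base composition and AT/GC strand skews per region class,
    start/stop codon tabulation and relative synonymous codon usage (RSCU)
    under the vertebrate mitochondrial code, pairwise Ka/Ks by the
    Nei-Gojobori (1986) pathway-counting method with Jukes-Cantor correction,
    tandem-repeat detection in control regions, and uncorrected p-distance and
    variable-site counts on aligned sequences. Includes a seeded synthetic
    mitogenome generator (37-gene vertebrate layout, configurable composition,
    planted repeats, controlled synonymous/nonsynonymous divergence) so the
    whole pipeline is testable without downloads, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
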