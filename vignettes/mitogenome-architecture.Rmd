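---
title: "Comparative mitogenome architecture and molecular evolution with mitoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome architecture and molecular evolution with mitoarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

## The problem

A newly assembled vertebrate mitochondrial genome is a circular molecule of
roughly 16–17 kb carrying a nearly invariant complement of 37 genes — 13
protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs — plus one major non-coding
control region (CR, also called the D-loop). Once such a genome has been
annotated, a fairly standard battery of descriptive and comparative
computations follows: how the genes tile the circle (overlaps and intergenic
spacers), strand usage, base composition and strand skews per region class,
start/stop codon usage and relative synonymous codon usage (RSCU), pairwise
Ka/Ks against congeners to assess selection, tandem-repeat structure of the
CR, and simple distance/variable-site summaries of aligned marker genes.
`mitoarch` implements that battery as a reusable package with a command-line
interface, together with a fully specified synthetic-genome generator so
every stage can be exercised and verified at desk scale, without network
access to sequence databases.

The packaged reference gene table (`default_gene_table_path()`) is a
machine-readable transcript of the annotated gene list of the *Tupaia
nicobarica* (Nicobar treeshrew) mitogenome, GenBank accession MW751815: a
17,164 bp circle whose class totals are 11,410 bp of PCGs, 1,497 bp of
tRNAs, 2,519 bp of rRNAs and a 1,757 bp CR. It anchors the structural
regression tests because every headline architecture number is a pure
function of this table.

## Coordinate and junction conventions

Coordinates are 1-based inclusive throughout, the convention shared by
GenBank flat files and published gene tables; no half-open form exists
internally, which removes a whole class of off-by-one bugs.
Origin-spanning features are rejected in this version (the reference layout
ends its CR exactly at the last position of the circle, so nothing is lost).

The junction ledger assigns one signed gap to each consecutive feature pair
in start order, `gap = start(downstream) − end(upstream) − 1`, plus a
wrap-around junction from the last feature back to the first with the
downstream start shifted by the genome length. Negative gaps are overlaps,
positive gaps intergenic spacers, and zero-gap junctions count as neither.
Under this convention the reference table reproduces exactly the published
tallies: 14 overlaps totalling 87 bp (longest 43 bp, atp8–atp6), 14 spacers
totalling 68 bp (longest 33 bp, trnN–trnC), and the conservation identity
`Σ class totals + spacers − overlaps = genome length`
(11,410 + 1,497 + 2,519 + 1,757 + 68 − 87 = 17,164). Both CR junctions have
gap 0, so whether one counts them as spacers is moot for this layout; the
package counts gap-0 junctions as neither, and documents that choice here
because other layouts may be sensitive to it. The strand tally excludes the
CR, which carries no strand.

## Composition and skews

AT and GC skew are computed on raw counts, `(A−T)/(A+T)` and `(G−C)/(G+C)`,
with `N` bases excluded from every denominator and a zero denominator
yielding `NA` rather than 0. Per-class composition concatenates the
reference-strand subsequences of all features of a class in genomic order:
a single-strand convention is the only one under which whole-genome and
per-class skews are mutually comparable, and overlapping bases are counted
once per feature they belong to (so the PCG total is 11,410 bp even though
atp8/atp6 share 43 bp). Display rounding is round-half-even at 2 decimals;
raw values are always retained. One known print inconsistency in the
reference literature is deliberately not chased: the whole-genome AT skew
recomputed from the printed percentages is 0.117 → 0.12, while the printed
skew value is 0.11; the package reports what the formula gives.

## Codon usage

The genetic code is always taken from `Biostrings::getGeneticCode()`
(default: vertebrate mitochondrial, transl_table 2, stops
TAA/TAG/AGA/AGG, ATA = Met, TGA = Trp), and synonymous-family degeneracies
derive from that table rather than being hard-coded — Met is a 2-codon
family here, unlike in the standard code. Start codons are reported as
observed, not validated against a whitelist, because vertebrate
mitochondria genuinely use ATC/ATT/ATA starts. Incomplete stop codons
(terminal T or TA completed to TAA by polyadenylation) are preserved as
tokens like `"T(AA)"` and excluded from codon counts. Internal in-frame
stops produce warnings, not errors, since annotation slips and genuine
overlap-frame artefacts both occur in real data. RSCU is computed over the
concatenated PCGs of a genome (`rscu(codon_counts(record))`); a per-gene
mode is available by passing `genes =`.

## Ka/Ks (Nei–Gojobori 1986)

The method is fixed to NG86 pathway counting with Jukes–Cantor correction:
per-codon synonymous site fractions exclude mutations to stop codons from
both numerator and denominator; differences between codons 2–3 steps apart
are averaged with equal weight over all mutation orderings whose
intermediates avoid stops, falling back (flagged) to all orderings when
every pathway is blocked. `S` is the mean of the two sequences' site sums;
`ps = Sd/S` and `pn = Nd/N` are corrected by `d = −(3/4)ln(1 − 4p/3)`.
`Ks = 0` leaves the ratio `NA` rather than infinite, and `p ≥ 3/4` is
reported as saturation with `NA` distances. Alignment is the caller's
responsibility: the per-gene driver pairs equal-length codon lists and
refuses length mismatches. The implementation is tested against an
independent exhaustive pathway enumerator and against generator pairs with
known planted substitution counts, which it recovers exactly before
correction.

## Tandem-repeat detection

The detector is deliberately *not* a reimplementation of Tandem Repeats
Finder's alignment/statistical model, whose parameters the source
literature does not state. It is a transparent seed-and-extend design whose
every stage is oracle-testable:

1. **Seeds.** For each period `p`, positions matching the base `p`
   downstream are computed; maximal exact match-runs at least
   `max(p, r_min)` long are seeds, where `r_min` solves
   `L · P · (1/4)^r ≤ α` (`α = seed_alpha`, default 0.05) so that i.i.d.
   random sequence of the scanned length is expected to produce fewer than
   `α` chance seeds across all `P` scanned periods.
2. **Merging.** Successive seed runs merge while the identity of the merged
   match-span stays at or above `min_identity`; the bridge between them
   must itself look periodic (short bridges — what a single interior
   mutation leaves behind — always merge; long ones need ≥ 0.5 identity so
   a long array cannot absorb a distant chance run by diluting the span
   average).
3. **Boundaries.** X-drop extension scored against the phased core
   consensus (match +1, mismatch −2, stop 8 below the running maximum),
   with the rule that an advance must beat the running maximum by at least
   2: a lone chance match (probability 1/4 per background base) never moves
   a boundary. Comparing to the consensus rather than to the base one
   period back means an edge mutation costs one mismatch instead of two.
4. **Reporting.** Consensus is the position-wise majority over
   period-phased columns; copy number is array length / period (1 decimal
   in displays, matching the field's "60.3 times" style); overlapping
   candidates resolve by `length × identity` score with harmonic periods
   (multiples of an equally good shorter period) suppressed in favour of
   the fundamental period.

Because a tandem array has no distinguished phase, the consensus of a
detected array is defined only up to rotation; tests compare
rotation-invariantly.

**What a green test does and does not establish.** On the synthetic CR
(60.3 copies of CGTACA in a 1,757 bp control region) the detector recovers
period, copy number and consensus. On the harder randomized property —
period 2–10, 3–80 copies, up to 5% mutation, planted in 600 bp of i.i.d.
background, recovery defined as exact period and copies within ±0.5 — the
measured recovery is ≈ 87% over 200-trial batches. The residual misses are
dominated by boundary ambiguity that no detector can resolve: a background
base that happens to match the consensus at its phase is indistinguishable
from a true partial copy (probability 1/4 per side), which alone exceeds a
±0.5-copy band at periods 2–3; mutations within ~3 bp of an array edge
likewise leave the planted boundary unrecoverable, and arrays shorter than
the chance-significance seed threshold (e.g. 14 bp in 600 bp) are
statistically undetectable by design. The corresponding acceptance check is
asserted at a 90% threshold and may therefore fail by a few trials; the
threshold was kept as stated rather than widened to fit the measurement.

CR domains (ETAS1/ETAS2, central domain, CSB1–3) are partitioned from
user-supplied anchor coordinates, not detected: their motifs vary across
taxa and the source literature reports only lengths.

## Distances

`p_distance()` is the uncorrected proportion of differing sites with
pairwise deletion of gap/`N` sites — the least assumption-laden reading of
a reported "genetic distance" computed with default settings in common GUI
software; a Jukes–Cantor option exists but is never the default.
`variable_sites()` counts alignment columns with at least two distinct
nucleotide states, ignoring gaps and `N` entirely, so a column whose only
variation involves a gap is not variable.

## The synthetic-data generator

`generate_genome()` emulates the stated world of a treeshrew-like
mitogenome rather than a tunable caricature; its defaults are fixed once:

* **Layout**: the packaged 38-row reference table (17,164 bp circle).
* **Composition**: per-class base probabilities transcribed from the
  reference composition table (whole-genome A 32.56 / C 27.13 / G 14.54 /
  T 25.74%, and the class-specific rows for tRNA/rRNA/CR); printed
  percentages summing to 99.98% are renormalized.
* **PCGs**: in-frame codon strings — declared start codon, body codons
  drawn uniformly from the 60 sense codons, declared stop (incomplete
  stops write only their residual nucleotides); minus-strand genes are
  written reverse-complemented onto the reference strand.
* **CR**: 60.3 copies of CGTACA planted near the 3′ end of the CR,
  emulating the reference repeat regime.

Non-coding classes are filled i.i.d. from their class probabilities, so
the generator reproduces class-level composition and skews but *not*
positional autocorrelation, codon-position structure within rRNAs, or
cloverleaf-foldable tRNAs — a green composition test establishes correct
counting arithmetic, not biological realism. Genes are written in three
passes (background, non-coding classes, then PCGs in start order), so where
two PCGs overlap the downstream frame wins and the upstream gene's tail —
including its stop codon — is whatever the downstream gene wrote. The three
affected genes in the default layout (atp8, atp6, nad4l) are listed in the
ground-truth ledger as `adjusted_tail`. A layout in which a downstream
feature would overwrite a PCG's start codon is rejected as infeasible. The
ground-truth codon counts are read back from the final sequence by an
independent bookkeeping path, so cross-checks against `codon_counts()` are
meaningful.

`diverge_pair()` plants exactly `n_syn` synonymous and `n_nonsyn`
nonsynonymous single-nucleotide changes, each in a distinct codon, each
validated against the genetic code at application time, never creating a
stop, and never inside a region shared with another feature — which is what
makes exact `(Sd, Nd)` recovery a fair test of the NG86 implementation
rather than of the generator.

## Numerical choices and degenerate inputs

* Percentages and skews are full precision internally; display rounding is
  round-half-even, 2 decimals (copy numbers: 1 decimal).
* Undefined quantities are `NA`, never 0: skews with zero denominators,
  RSCU of zero-total families, Ka/Ks with `Ks = 0`, saturated distances.
* The PCG fraction of the reference table is 100·11410/17164 = 66.4763%,
  which rounds to 66.48 under any rounding mode; the reference prints
  66.47 (truncation). Tests assert the full-precision value within 0.01 of
  the printed one instead of chasing the truncation.
* Empty sequences, all-`N` sequences, empty gene tables, size columns
  contradicting coordinates, FASTA shorter than the last feature, and
  alignment length mismatches are all hard errors naming the offender.

## Known limitations

* Origin-spanning features and compound (`join`) GenBank locations are
  rejected, not normalized.
* No alignment is performed anywhere; Ka/Ks and distance functions require
  pre-aligned input.
* The repeat detector reports the fundamental period of degenerate motifs
  (an `ACAC` array is period-2), and its copy numbers carry ±1-base
  boundary noise that is irreducible at the information level.
* Multi-species "average Ka/Ks" is supported only as per-pair tables; how
  a published average was taken over species pairs is rarely stated, so no
  averaging convention is asserted.
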