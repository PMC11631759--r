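---
title: "Quantifying prime-editing outcomes and MMR off-target signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prime-editing outcomes and MMR off-target signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primeout)
```

## The analysis problem

Prime editing installs small programmed edits (substitutions, short
insertions and deletions) via a Cas9 nickase–reverse transcriptase fusion
guided by a pegRNA. When single embryos are edited and their target locus
amplicon-sequenced to a depth of ~10,000 reads, each embryo is a mosaic:
some reads carry the intended edit, some are unedited, and some carry
unintended byproducts. Two byproduct families dominate double-nick
(complementary-strand nicking) strategies: deletions that remove sequence
between the two nick sites, and "combined" molecules carrying the
intended edit plus a 3' deletion. On top of the biology sits a technical
background — PCR errors from a high-cycle, inhibitor-tolerant polymerase,
sequencing errors, and somatic variation — that makes a few percent of
reads from *unedited* embryos look like errors.

`primeout` implements the full classification chain and the downstream
statistics, plus a family-based whole-genome stage that screens for the
mutational footprint of transiently inhibiting DNA mismatch repair (MMR):
an excess of short deletions at poly(A/T) homopolymer tracts, the classic
replication-slippage signature.

## Read preprocessing

The pipeline order is fixed: demultiplex → quality masking → ambiguity
filter → seed filter. Every read ends in exactly one bin, and the bins
partition the input (a property the tests assert).

* **Demultiplexing** assigns a read to the unique sample whose barcode is
  within Hamming distance 1 of the read's 20-nt barcode. A read matching
  no barcode, or more than one, stays unassigned: sample identity is
  never guessed. Validated barcode sets are pairwise distance ≥ 3, which
  makes distance-≤1 assignment unambiguous by construction.
* **Masking** replaces base calls with Phred quality < 30 by `N`.
  Masked calls are treated as *non-informative* everywhere downstream:
  they are excluded from identity computations and never generate
  variant events. The threshold is strict (`q = 29` masks, `q = 30`
  does not).
* **Ambiguity filter**: reads with more than 10% `N` among positions
  mapping to ±40 bp of the edit site are discarded. Reads are anchored
  ungapped at amplicon position 0 (amplicon primers guarantee this), and
  the interval is two-sided; the filter runs before alignment, as a
  cheap guard against low-quality reads that would otherwise inflate
  error rates.
* **Seed filter**: the first 40 read bases are compared (ungapped,
  `N`-excluded) to the first 40 amplicon bases; reads below 90% identity
  are removed, as are reads whose seed is more than half masked (an
  uninformative seed cannot validate a read). Identity is ungapped
  because the comparison precedes alignment. The seed must not overlap
  the edit or nick sites; amplicon designs keep those at least 75 bases
  from the read start, and the package rejects configurations that
  violate this.

Boundary semantics follow the filter definitions exactly: the ambiguity
filter discards strictly above 10%; the seed filter discards strictly
below 90%.

## Alignment

Kept reads are globally aligned to the wild-type amplicon with a
Needleman–Wunsch/Gotoh affine-gap aligner (compiled, three-state
dynamic program): match +1, mismatch 0, gap opening −3, gap extension
−1, a gap of length $L$ costing $-3 - (L - 1)$. End gaps are penalized
(true global mode). Two numerical choices make classification
deterministic:

* **Tie-breaking**: traceback prefers diagonal > vertical > horizontal
  moves, so among equally optimal alignments one is always selected
  reproducibly.
* **`N` handling**: `N` scores as a mismatch during dynamic programming
  but an aligned column containing a read `N` never becomes a
  substitution event.

The test suite checks score optimality against an exhaustive path
enumerator on random short sequence pairs, plus symmetry, affine
additivity and reconstruction invariants. For reads with the same length
as the amplicon and at most six informative mismatches, the classifier
uses a short-cut that reads events off the ungapped comparison; this is
exact, not approximate — for equal-length sequences any gapped global
alignment with $g \ge 1$ gaps scores at most $L - 3g - 4 < L - m$
whenever $m < 3g + 4$, so the ungapped alignment is strictly optimal
there.

## Outcome classification

Classification windows are anchored at the nicks: a 40-nt window around
the pegRNA nick (18 nt 5', 22 nt 3') and, for method 1 (double-nick
experiments), an additional 34-nt window around the secondary nick
(17 nt each side). Method 2 uses only the pegRNA-nick window. Windows
are half-open, 0-based; an insertion belongs to a window iff its
left-flanking reference base does.

Within the considered window(s) each read is binned:

* **WT** — no informative events;
* **PRECISE** — events exactly equal to the intended edit and nothing
  else;
* **ERROR** — any other non-empty event set.

Method 1 uses union semantics: an event in either window makes the read
an error, and a precise call requires the secondary window to be
event-free. Event comparison happens on *left-normalized* indels so
that equivalent alignments of the same molecule (e.g. a deletion inside
a homopolymer) match the intended edit consistently. Changes strictly
outside all considered windows are deliberately ignored — the windows
exist to keep background SNPs from dominating error rates.

Per-embryo fractions use kept reads as the denominator (the filters
typically retain well over 90% of reads). One consequence worth knowing:
a precise-edit read whose edit-site base call was masked carries no
informative event and bins as WT, so heavy masking would deflate precise
fractions; with the quality levels used here the effect is negligible.

## Background model and statistical calls

Unedited control embryos yield a 1–6% background of error-classified
reads. Per target site and method, the control error fractions are
modeled as a normal distribution (mean, n−1 sd). Calls then follow:

* **Precise-edit detection**: strict cutoff, positive iff
  `frac_precise > 0.01` on the raw fraction; the boundary is assigned
  to unedited.
* **Adjusted errors**: `max(0, frac_error − control mean)`; clipping at
  zero covers the case where a sample sits below the control mean.
* **Error significance**: one-sided upper-tail z-test,
  `z = (frac_error − mean) / sd`, Bonferroni-gated at
  `p < 0.001 / m_tests`. The family size `m_tests` defaults to the
  number of embryos tested in the same call and can be overridden; a
  degenerate background (sd = 0 from a tiny control group) is floored at
  1e−6 with a warning rather than failing.
* **Group comparisons**: two-sided two-sample t-tests (pooled-variance
  Student or Welch), delegated to `stats::t.test`; constant groups fall
  back to a floored-variance closed form. Predicted-vs-observed
  efficiency comparisons report Pearson's r with the t-based two-sided
  p-value and the least-squares fit.

## Family WGS stage

The input is a joint-genotyped multi-sample VCF (per-sample GT/AD/DP), a
pedigree/treatment sheet, and the reference. Records are decomposed to
biallelic rows and indels left-aligned before any rule runs, because the
uniqueness and adjacency rules are allele-level. A **unique variant** is
detected in exactly one family member (non-reference genotype, all other
members called homozygous reference — missing genotypes disqualify a
site), with depth ≥ 30 in *every* family member, carrier variant allele
frequency ≥ 0.2, autosomes only (the excluded-chromosome list covers
X/Y aliases and RefSeq-style accession names, and is configurable).

Downstream summaries: indel typing by `length(alt) − length(ref)`
(multi-nucleotide substitutions count as SNVs); the fraction of unique
−1 bp deletions whose deleted base lies in or immediately abuts a run of
≥ 4 identical A or T bases (`min_tract = 4` is configurable; the
signature is defined qualitatively in the field, and 4 is the shortest
run length commonly called a homopolymer tract — samples with no −1 bp
deletions report `NA`, not 0); per-region variant counts with a 100-bp
pad for predicted off-target sites and no pad for microsatellite
regions; and the per-treated-sample unique-indel count relative to the
control-group mean, with a Welch test on the counts (a zero control mean
flags the fold as undefined).

## Synthetic data: what it emulates, and what it does not

The generators make every stage testable without downloads and ship
ground-truth manifests. They are pure functions of (configuration,
seed).

`simulate_embryo_reads()` draws each read's molecule from a mixture over
{WT, precise, inter-nick deletion, combined edit + 3' deletion, small
nick indel}, applies i.i.d. substitution noise and two-valued qualities.
Defaults are the study conditions: depth 10,000; substitution rate
5e−4 per base, which puts the expected error-read fraction for a 40-nt
window at $1 - (1-5\times10^{-4})^{40} \approx 1.98\%$, inside the 1–6%
control band; a PE4-like mixture (60% precise, ~3% byproducts).
Inter-nick deletions are anchored at the pegRNA nick and extend a
uniform 1..(nick distance) bases toward the secondary nick — this is how
double-nick excision behaves and it guarantees every byproduct molecule
is visible to the classification windows (a deletion confined to the gap
*between* the two windows would be undetectable by construction, which
is a limitation of the windowed method itself, not of the simulation).
The quality model is two-valued (high 37, low 11, low probability 5e−4):
masking behavior is what needs exercising, and the low rate keeps
masking from measurably deflating outcome fractions (see above). The
generator does not model PCR chimeras/jackpots, read-length effects, or
indel sequencing errors — so passing tests demonstrate correctness of
the classification machinery under substitution noise, not robustness
to every failure mode of real libraries.

`simulate_family()` builds a toy genome (two 100-kb autosome-like
contigs plus a 50-kb sex-like contig, so the exclusion rule is
exercised) seeded with A/T homopolymer tracts (5 per kb, lengths 4–10,
flanked by a different base so each tract is a maximal run). It plants
shared variants (≥ 2 carriers), unique SNVs (Poisson mean 60 per
sample), and unique indels: Poisson mean 40 per control sample, treated
offspring at fold 2.5, with 70% of the treated excess as −1 bp deletions
abutting A/T tracts. Carrier allele fractions are drawn in 0.3–0.6
(clear of the 0.2 gate), depths around 100× (the study's coverage),
and a labelled 2% of planted variants deliberately violate the depth
rule so the filter's rejections are testable, alongside chrX plantings
and multi-carrier sites. Indel records are emitted already
left-normalized (the round-trip test asserts `load_family` changes
nothing). Scale is the main simplification: a 250-kb toy genome with
hundreds of variants stands in for a 2.7-Gb genome with thousands; rates
per sample, not per base, are matched to the analysis.

## Problem sizes and tolerances used by the test suite

The acceptance-style tests run, per check: 500 random pairs against the
alignment enumerator; 20 embryos at depth 10,000 for mixture recovery
(tolerance ±2 percentage points against the realized per-embryo truth);
an 8-embryo control cohort at depth 10,000 for the background closed
form (±0.5 points); 1,000 null embryos for z-test calibration (≤ 0.2%
flagged at α = 0.001, m = 20); 1,000 random 50 × 6 tables against a
brute-force unique-variant oracle; 10 simulated families for fold-change
recovery (mean within 20% of 2.5); and one family for homopolymer-flag
sensitivity/specificity (exact). These sizes keep the default suite in
the low minutes on a single core while leaving the stochastic checks
with comfortable statistical margins — except mixture recovery at 90%
precise, which is intentionally tight: the ~1.96% window-noise deflation
consumes most of the 2-point budget, exactly as it does in real data.

## Known limitations

* Reads are assumed to start at amplicon position 0; there is no
  general primer/adapter discovery.
* The windowed method cannot see changes strictly outside its windows;
  large structural variants and pegRNA scaffold insertions are reported
  simply as ERROR (or not at all if entirely outside).
* The background model is normal by construction; with very few control
  embryos the sd floor, not the data, sets sensitivity.
* Uniqueness uses genotype calls, not raw allele support, to define
  detection in non-carriers; low-level contamination in a "reference"
  sample would not disqualify a site.
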