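---
title: "Imputing KIR copy number from phased SNP haplotypes: models and methods"
author: "kirimp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing KIR copy number from phased SNP haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirimp)
```

## The imputation problem

KIR haplotypes in European populations are, to a good approximation,
composed of one centromeric gene-content motif (cA01, cB01, cB02) and one
telomeric motif (tA01 with or without the *KIR2DS4* deletion, tB01), joined
at the recombination hotspot between *KIR3DP1* and *KIR2DL4*. Copy number
at each of the 17 typed loci is determined by the motif pair; the broad
`AvsB` classification calls a haplotype A exactly when both motifs are the
designated A motifs, and the fine-grained `KIRhaplotype` label names the
gene-content class itself. SNPs on the genotyping array sit inside or
between KIR genes and are in strong but imperfect linkage with the motifs,
so a haplotype's phased alleles carry most of the information about its
KIR content. Imputation is the supervised problem of learning that mapping
from a reference panel and applying it to new phased haplotypes.

## The classifier

`kir_imputer()` fits one classification-tree ensemble per locus:

* **Trees.** CART-style recursive partitioning on binary phased alleles;
  splits are two-way (allele 1 left, allele 2 right). The split criterion
  is Gini impurity decrease, evaluated as the equivalent child-purity score
  $\sum_{\text{child}} (\sum_c n_c^2)/n$ so that an exhaustive search using
  the same arithmetic reproduces the implementation bitwise (the unit tests
  exploit this). A node becomes a leaf when it is pure, no candidate split
  strictly improves purity, or an optional node limit is reached. Leaves
  predict the bootstrap-majority class, ties going to the first class in
  sorted label order.
* **Bagging.** Each tree trains on a with-replacement resample of size
  $N$; the per-tree in-bag counts are stored, which makes out-of-bag (OOB)
  prediction, OOB accuracy and permutation importance exact recomputations
  rather than approximations.
* **Attribute bagging.** At every node a fresh subset of `mtry` SNPs is
  drawn without replacement; only these are candidates for the split.
  Exact score ties resolve to the smallest SNP index regardless of draw
  order, which keeps fits reproducible.
* **Prediction.** One hard vote per tree; the reported probability is the
  vote fraction, so rows sum to one exactly. MAP ties break to the first
  class in canonical (sorted) order.

All ensemble randomness comes from a private Mersenne-Twister stream seeded
per fit, so results are bit-identical for a given seed and independent of
the session RNG; `cross_validate()` and multi-locus fits derive
per-fold/per-locus seeds arithmetically from the master seed.

### Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `ntree` | 1000 | accuracy is flat beyond a few hundred trees; 1000 keeps vote fractions reasonably fine-grained |
| `mtry` | 100 for panels of ≥ 200 SNPs; 10 for ≤ 15 SNPs; $\lfloor\sqrt p\rfloor$ otherwise | several loci are informed by only one or two SNPs, and a small subspace leaves many trees without any of them; a large subspace fixes this without collapsing ensemble diversity. For a ~300-SNP panel the square-root fallback is 17 |
| `max_nodes` | unlimited | tree size does not measurably affect accuracy on these panels |
| calling threshold | caller's choice, comparison is `>=` | a call is made exactly at the threshold; accuracy is computed over called units only |

## Reference-panel construction from families

Family cohorts yield phased haplotypes but also haplotypes identical by
descent, and typing sets (KIR versus SNP) overlap only partially. The
builder therefore: (1) assigns a parent of origin to every offspring
haplotype separately from KIR types (exact vector match) and SNP
haplotypes (Hamming distance strictly below 20, tolerating residual
phasing and genotyping error); (2) merges the two evidence sources,
excluding haplotypes with conflicting or ambiguous evidence — this is
deliberately conservative; (3) prunes relatives: with both parents typed
only parental haplotypes are kept; with one parent, that parent plus
offspring haplotypes not present in the parent, deduplicated among
offspring by exact KIR-and-SNP content; with no typed parent, deduplicated
offspring haplotypes. Only haplotypes with complete SNP **and** KIR data
enter the final panel; every exclusion is logged with a reason.

## Harmonising external panels

Query panels from other arrays are matched to the reference by GRCh37
position (SNP identifiers differ across platforms). Allele coding is
reconciled by nucleotide identity, then by purine/pyrimidine strand
complement; strand-ambiguous pairs (A/T, C/G) are oriented by allele-1
frequency agreement within `freq_tol` (default 0.1) and dropped when the
frequencies cannot decide — near-0.5 frequencies are never guessed.
Positions absent from the reference, or with irreconcilable allele pairs,
are dropped and reported as absent.

## Evaluation machinery

* **Cross-validation** partitions haplotypes into near-equal folds by a
  seeded shuffle. Folds are assigned per haplotype; the two haplotypes of
  one individual may land in different folds, which matches the unit of
  analysis (the haplotype) but mildly flatters accuracy when whole
  individuals would be imputed in practice.
* **Credible intervals** are equal-tailed quantiles of the
  Beta$(k+1, n-k+1)$ posterior (binomial likelihood, uniform prior). Under
  cross-validation the independence assumption is only approximate because
  training folds overlap; intervals should be read accordingly.
* **Calibration** bins imputations by MAP probability into ten equal-width
  bins spanning the *observed* MAP range (a degenerate range collapses to
  one bin) and asks whether the bin's mean MAP lies inside the Beta
  interval of its observed accuracy.
* **Per-individual accuracy** for unphased validation data sums the two
  per-haplotype MAP copy-number calls and scores the total against the
  measured total. Summing MAPs (rather than taking the MAP of the summed
  distribution) is the primary definition; both views are easy to build
  from the returned probability tables.
* **Expected per-individual accuracy** under random pairing averages over
  100 seeded random disjoint pairings by default; the estimator's
  expectation equals the exhaustive-pairing mean, which the tests verify by
  enumeration at small $n$.

## SNP selection

Permutation importance follows Breiman's scheme: for each tree, OOB
accuracy on the actual data minus OOB accuracy after permuting one SNP's
alleles *within that tree's OOB set* (one fresh permutation per tree and
SNP), averaged over trees and divided by the standard deviation of the
per-tree drops. SNPs never used by any tree score exactly zero. Permuting
within the OOB set per tree is the cited original scheme; permuting across
all samples gives indistinguishable rankings in practice but a less clean
null. The removal experiment re-ranks after every removal by default
(`rerank = FALSE` reproduces the fixed-initial-ranking variant); the
removed-set model is fitted with `mtry` equal to the removed-set size. The
"minimal number of SNPs for high accuracy" per locus is a user decision in
the primary interface, mirroring how such sets are chosen by inspection;
the per-locus counts plus a poor-clustering exclusion flag produce the
final selected set.

## The synthetic generator

`kir_sim_spec()` encodes the generative model the tests and the acceptance
script run against: haplotypes drawn as independent (centromeric,
telomeric) motif pairs — optionally coupled through a linkage parameter —
with per-locus copy numbers a deterministic function of the motif pair;
each SNP tags its side's motif via a motif-specific base allele, reported
correctly with probability `tagging` (default 0.99) and flipped again with
probability `error_rate` (default 0.005, a realistic post-QC genotyping
error); default sample size 500 haplotypes and 150 + 150 SNPs, the scale
of a family-derived reference panel on a dense immune-region array.
Default motif frequencies (cA01 0.55, cB01 0.25, cB02 0.20; tA01del 0.40,
tA01wt 0.20, tB01 0.40) are in the range reported for European cohorts.
`long_tail_freqs()` substitutes a geometric frequency spectrum so that
class training counts span below 10 to above 100, the regime where the
dependence of per-allele sensitivity on training count becomes visible.
Families draw founder haplotypes from the same model, children inherit one
haplotype per parent uniformly with no within-region recombination, and
per-member missingness emulates partially overlapping typing sets.
Validation cohorts expose phased SNPs but only per-individual copy-number
totals.

What the generator does **not** emulate: linkage-disequilibrium decay and
recombination within motifs, allelic (sequence-level) variation inside KIR
genes, genotype-intensity data, population structure, and motif classes
absent from the reference. Passing tests therefore demonstrate that the
machinery is correct under the stated generative assumptions — not that
real-data accuracy will match the synthetic numbers.

### A note on probability calibration

Vote fractions are conservative when the SNP signal is highly redundant.
At the generator's defaults (~300 SNPs tagging five motifs at 0.99), the
motif is essentially always recoverable, so observed accuracy is ~1.0 in
every MAP bin while vote fractions range well below 1: the sub-unit
probabilities reflect ensemble randomness, not data ambiguity, and the
strict bin-wise calibration check fails by construction in this regime.
With genuinely ambiguous classes (rare labels under a long-tail spectrum,
weaker tagging) the probabilities become informative and mildly
conservative — the behaviour expected of random-forest vote fractions.

## Numerical choices and degenerate inputs

* Exact split-score ties → smallest SNP index; MAP and leaf-majority ties
  → first class in sorted label order; tag-SNP ties → smallest genomic
  position. All deterministic.
* Gain must exceed the parent score by $10^{-12}$ to split; constant SNPs
  can never split, so no SNP repeats on a root-to-leaf path.
* Single-class targets yield degenerate always-that-class models with a
  warning (framework loci such as *KIR3DP1* and *KIR2DL4* hit this path).
* Missing alleles are tolerated on read but refused at fit time with an
  instruction to impute or drop upstream — silent imputation would hide
  data problems.
* The unpaired haplotype in pseudo-individual construction is the one left
  after the seeded shuffle.
* Coordinates are 1-based inclusive GRCh37; region filters are closed
  intervals.

## Problem sizes

The test suite exercises the full pipeline at reduced sizes (tens to a few
hundred haplotypes, 10–80 SNPs, 25–300 trees) chosen so each property is
decisively testable, and the panel-scale checks (500 haplotypes, 300 SNPs,
1000 trees, 5-fold cross-validation over all 19 loci, three seeds) run in
about a minute on one core thanks to the compiled tree ensemble. The
acceptance script uses the generator's defaults unchanged.

## Known limitations

Only variants present in the reference panel can be imputed, and rare
classes are imputed poorly — per-allele sensitivity rises sharply with
training count. The model ignores SNP intensity information and
sequence-level allelic variation. Probabilities should be thresholded, not
taken at face value, in high-redundancy settings (see the calibration note
above).
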