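---
title: "Light chain coherence in paired B cell repertoires: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light chain coherence in paired B cell repertoires: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repcoherence)
```

## The question the pipeline answers

B cell antigen receptors pair a heavy chain with a light chain. When two B
cells from different people carry the same heavy chain V gene and the same
CDRH3 amino-acid sequence (a "public" configuration), did they also end up
with the same light chain V gene? `repcoherence` quantifies this *light
chain coherence* from paired single-cell V(D)J data, separately for
computationally naive cells (no somatic hypermutation, SHM) and memory
cells (at least one SHM), cross-donor and within-donor, together with the
supporting machinery each step needs: donor V-allele inference, SHM
counting, a clonotyper, permutation nulls, transitive grouping, and
junction decomposition.

Throughout the package "CDRH3" denotes the junction-style amino-acid
string that retains the conserved cysteine and tryptophan/phenylalanine
(e.g. `CIKDILPGGADSW`); identity between CDRH3s is positional, because a
pair is only eligible when the lengths agree. All internal coordinates are
1-based closed intervals, the R/Bioconductor convention.

## The coherence statistic

Two cells form an *eligible pair* when they share the heavy V gene name and
the CDRH3 length and are both memory or both naive. Pairs are binned by
CDRH3 percent identity floored to the nearest 10%. Within a bin, coherence
is the fraction of pairs whose light V gene names match; duplicated-locus
paralogs whose names differ only by a "D" marker (`IGKV1-17` vs
`IGKV1D-17`) count as the same gene unless `merge_paralogs = FALSE`. Cells
appear in many pairs, so bins are summaries, not samples of independent
observations; the per-bin binomial standard error treats pairs as
exchangeable and should be read accordingly. Donor-pair stratification
(`coherence_curve(..., stratify_by = "donor_pair")`) gives the
between-stratum spread that a mean ± s.e.m. display needs.

Cross-donor scope requires the two cells to come from different donors.
Within-donor scope requires different computed clonotypes *plus* positive
evidence of separate recombination events: different light CDR3 lengths, or
framework-4 support for different heavy (or light) J genes — at least three
J-discriminating positions where each cell matches its own reference, and
no discriminating position where both cells support one and the same
reference. The veto clause is deliberately conservative: a shared J
signature at any informative position disqualifies the pair.

Three nulls and robustness checks accompany the curves:

* **Permutation null.** Light chains are permuted among retained cells
  (one per clonotype by default) with heavy chains fixed; coherence is
  recomputed per replicate. Under this null every bin's expected coherence
  is the probability that two distinct cells share a light V class,
  $\sum_g c_g(c_g-1)/(n(n-1))$, which is the usage concentration
  $\sum_g f_g^2$ up to $O(1/n)$. `permute_light_chains()` reports the
  exact form as `match_probability`.
* **Slope heterogeneity.** Differences between per-curve regression slopes
  of coherence on identity bin are tested with an extra sum-of-squares F
  test: a pooled-slope model (per-curve intercepts, one slope) against the
  full per-curve-slope model, computed directly from the two residual sums
  of squares so that degenerate cases (identical curves) return F = 0
  rather than a numerical artifact.
* **Label-swap robustness.** `swap_class_labels()` flips naive/memory for
  an exact fraction of cells, probing sensitivity to misclassification.

Association between heavy and light V usage at the clonotype level is
tested by Monte-Carlo simulation of the chi-square statistic of the
Vh/Vl contingency table (one count per clonotype), with
$p = (1 + \#\{T_{null} \ge T_{obs}\})/(B + 1)$ and $B = 100{,}000$ by
default. Gene-free coherence uses Levenshtein distance between light chain
nucleotide sequences (threshold 20 by default); the substrate is the
full-length light sequence, a documented choice where several substrates
would be defensible.

## Allele inference and naive/memory classification

Expressed repertoires mix germline variation with SHM, so SHM counting
needs donor-specific alleles first. For each donor and V gene the pileup
uses one representative cell per (CDRH3 length, CDRL3 length, partner V,
partner J) stratum — a clonality-robust heuristic that needs no clonotypes,
with the lexicographically smallest cell id as the deterministic
representative. A position is variant when a non-reference base occurs in
at least 4 selected cells and at least 25% of the pileup; the last 15 V
bases are excluded as junction-adjacent. Cell footprints over the variant
positions that meet the same two thresholds become alternate alleles; the
reference allele is always available and the number of alternates per gene
is not capped (duplicated gene copies can legitimately produce several).
Footprint-level thresholds reuse the position-level ones — the evidence
criteria are stated qualitatively in the field and this is the
interpretation we fixed; both are exposed as parameters.

Each chain is then assigned the allele (reference or alternate) minimizing
mismatches over its V region, ties resolved toward the reference with an
ambiguity flag. SHM is counted as substitution mismatches outside the
junction: over the V region up to the same 15-base tail exclusion, plus
FWR4 against the J reference. Indels are not modeled. A cell is *naive*
iff its total is zero, on both chains. This is a biological
simplification — class-switched cells without V mutations would still be
called naive — which is exactly why the label-swap robustness check
exists.

The clonotyper is a documented stand-in for heavier tools: within a donor,
single-linkage over cells sharing heavy V and J, light V and J, and both
junction lengths, linking pairs whose concatenated heavy+light junction
nucleotide identity is at least 0.85. Clonotypes never span donors.
Connected components are computed with igraph; the test suite checks the
partition against an independent breadth-first-search oracle.

## Transitive grouping

Beyond pairs, cells are grouped by the transitive closure of a similarity
relation: same clonotype, or same heavy V gene with CDRH3 identity at or
above a threshold (90% by default). Scope is memory cells in all-memory
clonotypes. Groups are connected components, so lowering the threshold can
only merge groups — the partitions nest, a property the tests verify.
Group-level coherence is reported two ways, because both accountings are
informative: the fraction of cross-donor member pairs sharing the light V
class, and the fraction of member cells using the group's modal light
gene. Per-column Shannon entropies (bits) of equal-length CDR3 sets
support logo-style summaries; when a group mixes CDR3 lengths, profiles
should be computed on the modal length's sequences — the package does not
embed a multiple aligner.

## Junction decomposition

Each heavy junction is aligned globally against candidate reference
concatenations: V's junction tail (from the conserved C codon), zero, one,
or two D segments, and J's 5' region through the conserved W codon —
`1 + d + d(d-1)` candidates for `d` D genes. Scoring is match +1, mismatch
−1, gap of length L costs 2 + L; the alignment engine is Biostrings. The
highest score wins; ties prefer fewer D segments, then lexicographic D
names. A D segment must contribute at least 4 aligned matching bases or
the best simpler topology wins. For efficiency, VDDJ pairs are only formed
from each junction's 4 best-scoring single D genes, and all alignments are
batched elementwise — whole-repertoire decomposition runs in seconds, not
hours.

Inserted bases are junction bases aligned to reference gaps; reference
bases missing from the junction (end trimming) are counted separately as
deletions; the substitution rate divides mismatches by aligned
(match + mismatch) bases.

Two estimator properties deserve emphasis, because they are properties of
*any* such decomposition, not implementation defects:

* **Absorption.** When non-templated insertions sit next to trimmed
  reference bases, the optimal alignment often pays mismatches instead of
  a deletion-plus-insertion gap pair, so measured insertion counts
  undercount the generative insertion length under heavy trimming. In
  trim-free simulations recovery is exact (the tests assert this); under
  the default trimming the measured mean sits well below the generative
  mean.
* **Spurious VDDJ.** Long non-templated stretches occasionally contain a
  chance ≥4-base match to a second D gene, so the measured VDDJ rate
  overestimates the generative rate by roughly a percentage point at the
  default threshold. Raising `d_min_matches` trades this against missed
  genuine VDDJ events.

## The synthetic repertoire generator

Every stage is testable without any external download because the package
ships a generative model of paired repertoires with exact ground truth.
Per heavy chain: categorical V/D/J usage (geometrically skewed V usage),
geometric end-trimming, geometric N1/N2 insertions with two D segments at
a small VDDJ rate, junction frame forced to a multiple of three by a
mean-zero nudge of the last N stretch, and stop-codon-free junctions by
redraw (germline segments are generated free of stop trigrams in every
frame so redraws converge). Light chains are V(N)J with a conserved
phenylalanine. Memory cells receive a zero-truncated Poisson number of
substitutions uniformly outside the junctions — memory is *defined* as at
least one SHM, so the classifier's exact recovery is a closed-loop test of
the mutation counter, not a tautology about Poisson draws. Naive cells are
unmutated singletons; memory clone sizes are geometric with mean 2.

Defaults are calibrated to the study conditions the pipeline targets:
four donors of 5,000 cells each, mean total insertion length 5 nt, VDDJ
rate 0.5%, junction geometry giving a mean CDRH3 near 18 amino acids, and
light V usage with a background match probability near 0.08. These are
fixed properties of the simulated study, not tuning knobs.

Public recurrences are planted, not emergent: each key copies one heavy
configuration (V gene + CDRH3) into two cells — two donors for cross-donor
keys, two clones of one donor for within-donor keys. The first copy uses a
canonical light V drawn from usage; the partner uses the same light V
class with probability $(p - f_c)/(1 - f_c)$ and a background draw
otherwise, so the planted *pair* is coherent with probability exactly
`p_coherent` (a background draw can match by chance, and the calibration
accounts for it; a naive independent-copy scheme would square the
coherence instead). At `p_coherent = 0` the planted pairs match at the
background rate $\sum f^2$, which is what the naive planting uses.

What the generator does **not** emulate — and therefore what passing tests
do *not* show about real data: selection (coherence is planted, not the
outcome of antigen-driven dynamics), junction-region SHM (junctions are
preserved so CDR3-keyed recurrences survive exactly), insertion/deletion
SHM, biologically calibrated gene-specific trimming profiles, isotype
structure, and sequence-level light chain convergence (coherent partners
share the light V *gene* but draw their light junctions independently, so
nucleotide edit distances between planted partners run higher than real
convergent antibodies show). Conclusions about real repertoires need the
real per-cell tables; the pipeline reads them through
`read_per_cell_table()` with a user-supplied column mapping.

## Numerical choices and degenerate inputs

* Coherence of an empty pair set is `NA` with `n = 0`, never 0.
* All 11 identity bins are emitted even when empty (`n_pairs = 0`,
  fraction `NA`).
* `one_cell_per_clonotype()` and every stochastic stage take explicit
  seeds; rerunning a pipeline with the same configuration reproduces its
  JSON summary byte for byte.
* The slope F test drops curves with fewer than three populated bins and
  errors when fewer than two curves remain.
* The allele pileup truncates at the shortest selected sequence;
  footprints are only compared over covered positions.
* Sequences are compared positionally from the V 5' end; cells whose V
  region length disagrees with the reference outside the trimmed tail are
  not meaningfully comparable and should be filtered upstream (indels are
  out of scope).

## Problem sizes used by the tests and the acceptance script

The shipped checks run on simulated repertoires of 20,000 cells (four
donors) for coherence recovery, classification exactness and the headline
script; 5,000 memory cells for the permutation null at 1,000 permutations;
1,000 random references for the decomposition identity property; 100
random fixtures for the grouping oracle; and 1,000 random string pairs for
the edit-distance oracle. Junction decomposition in the acceptance script
runs on a uniform 3,000-cell subsample. These sizes were chosen so each
property is measured with comfortable statistical margin while the whole
suite stays quick on a laptop.
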