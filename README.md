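# repcoherence

Analysis pipeline for **light chain coherence** in paired single-B-cell
antibody repertoires.

When two B cells from different donors carry the same heavy chain V gene
and the same CDRH3 amino-acid sequence — a *public* heavy configuration —
how often do they also use the same light chain V gene? For naive B cells
(no somatic hypermutation) that probability is close to the chance level
set by light V gene usage, around 10%; for memory B cells it is dramatically
higher, around 80%. `repcoherence` computes this statistic and everything
it depends on, for repertoire immunologists working with paired V(D)J data
(AIRR Rearrangement TSVs or 10x-style contig annotations):

* **Germline V allele inference** per donor from expressed-sequence
  pileups: one non-redundant cell per (CDRH3 length, CDRL3 length, partner
  V, partner J) stratum; a variant position needs a non-reference base in
  ≥ 4 cells and ≥ 25% of the pileup, outside the last 15 V bases; cell
  footprints meeting the same thresholds define alternate alleles.
* **Naive/memory classification**: SHM counted as substitutions outside
  the junctions on both chains against the assigned allele; naive ⇔ zero.
* **A documented single-linkage clonotyper** (within donors; shared V/J
  genes, equal junction lengths, ≥ 85% combined junction nt identity).
* **Coherence statistics**: eligible-pair enumeration (same heavy V, same
  CDRH3 length, same class), identity bins floored to the nearest 10%,
  per-bin coherence curves with donor-pair stratification, a light-chain
  permutation null whose analytic mean is the usage concentration
  Σ f², an extra sum-of-squares F test for slope differences, a
  Monte-Carlo Vh/Vl contingency test, edit-distance coherence, cross-donor
  recurrence counting, and within-donor coherence guarded by
  independent-recombination evidence (CDRL3 length or FWR4 J-gene support).
* **Transitive grouping** of memory cells (same clonotype, or same heavy V
  with CDRH3 identity ≥ threshold, closed transitively) with group-level
  coherence and per-position CDR3 entropy profiles.
* **Junction decomposition** of heavy junctions against VJ / VDJ / VDDJ
  germline concatenations (up to two distinct D genes), counting inserted
  bases, deletions, and substitutions.
* **A synthetic paired-repertoire generator** with exact ground truth
  (gene usage, geometric trimming and N insertions, VDDJ events, SHM,
  clonal expansion, planted public recurrences at a tunable pair-level
  coherence), so the entire pipeline is testable offline.

## Worked example

Simulate a two-donor repertoire with 120 planted cross-donor public keys
at 80% pair coherence, classify, clonotype, and measure:

```r
library(repcoherence)

cfg <- sim_config(donors = 2, memory_per_donor = 400, naive_per_donor = 400,
                  n_public = 120, n_public_naive = 60, n_public_within = 0,
                  seed = 42)
sim <- simulate_repertoire(cfg)
cells <- classify_cells(sim$cells, reference = sim$germline)
cells <- compute_clonotypes(cells)
table(cells$cell_class)
#> memory  naive
#>    800    800

pairs <- enumerate_pairs(cells, "cross_donor", "memory")
coherence_curve(pairs, cells) |> dplyr::filter(n_pairs > 0)
#> # A tibble: 9 × 6
#>   curve   bin n_pairs n_coherent fraction     se
#>   <chr> <dbl>   <int>      <int>    <dbl>  <dbl>
#> 1 all       0      17          0   0      0
#> 2 all      10     468         32   0.0684 0.0117
#> 3 all      20     472         51   0.108  0.0143
#> # ...

mem100 <- pairs[pairs$bin == 100, ]
light_chain_coherence(mem100, cells)
#> [1] 0.8416667
#> attr(,"n")
#> [1] 120
```

The classifier found the expected 800 memory and 800 naive cells (every
simulated memory cell carries at least one SHM outside the junctions).
Pairs at low CDRH3 identity share a light V gene about 7–11% of the time —
the chance level — while the 120 pairs at 100% identity (the planted
public keys) are coherent 84% of the time, recovering the planted 80%
within sampling error. The permutation null confirms the chance level:

```r
null <- permute_light_chains(cells, n_perm = 200, seed = 42)
round(attr(null, "match_probability"), 3)   # analytic match probability
#> [1] 0.092
round(null$mean[11], 3)                     # permuted bin-100 coherence
#> [1] 0.092
```

Real data enter through `read_airr_rearrangements()` /
`read_10x_contigs()` + `assemble_cells()`, or a canonical per-cell TSV via
`read_per_cell_table()` (foreign headers adapted with its `col_map`
argument). `run_pipeline()` chains every stage and writes curves, group
tables, junction decompositions and a JSON summary.

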