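---
title: "Methods: SSR diversity, identity cards and stepwise core collections"
author: "ssrcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR diversity, identity cards and stepwise core collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrcore)
```

This vignette is the package's account of the methods it implements: the
statistical conventions, the algorithms, the genuinely open design choices
and how they were resolved, and what the synthetic-data validation does and
does not demonstrate.

## Data model

The pipeline's universal input is a rectangular accession × marker table of
diploid SSR genotypes (`ssr_matrix`). Alleles at a locus are letters A, B,
C, … in decreasing band molecular weight, the usual convention for
silver-stained PAGE scoring; a genotype is an unordered letter pair stored
canonically, a single observed band is scored homozygous, and a cell with
no band is missing as a whole. Two consequences of band-based scoring are
baked in deliberately: single-allele missingness is not representable, and
a locus's allele set is declared by the data (A up to the largest observed
letter) rather than by an external schema. At most nine alleles per locus
are supported — the bound the single-character identity coding imposes, and
far above what band-scored SSR panels resolve in practice.

`recode_bands()` converts raw per-accession band-weight lists into this
representation; `read_genotypes()`/`write_genotypes()` round-trip a
human-readable delimited dialect ("AB", "--") and 4-digit GenePop.

## Diversity statistics and their conventions

All per-locus statistics derive from gene-copy allele frequencies with
listwise exclusion of missing cells at that locus. Conventions that have
several defensible variants, fixed here once:

- **Expected heterozygosity** uses the unbiased correction
  $H_E = \frac{2n}{2n-1}(1 - \sum p_i^2)$ with $n$ the *per-locus* number
  of genotyped individuals. With missing bands $n$ varies by locus, which
  is why $H_E$ is not a constant multiple of Nei's $D$ across a panel.
- **Shannon index** uses the natural log.
- **PIC** is Botstein's codominant form,
  $1 - \sum p_i^2 - \sum_{i<j} 2p_i^2p_j^2$; it always satisfies
  $PIC \le D$, which the tests assert as an invariant along with the exact
  identity $D = 1 - 1/N_e$ (both are computed from the same frequency
  vector, so the identity holds to machine precision).
- Reported tables round to 4 decimals; computation is never rounded.

On subsets (cores), frequencies are reported over the full collection's
declared allele labels, so Na counts alleles actually present in the
subset — the quantity core-retention percentages need.

## Distances and UPGMA

Individual accessions are clustered on the **allele-sharing distance**
(1 − proportion of alleles shared, counted with multiplicity, averaged
over the loci typed in both individuals). This was a real design choice:
frequency-based distances such as Nei's (1972) standard distance are
defined on populations and degenerate for single diploids, so the package
follows the PowerMarker practice of shared-allele distances for individual
trees while still providing `nei_1972_distance()` for group-level
comparisons. Missing loci are deleted pairwise per accession pair rather
than listwise; with several percent missing bands, listwise deletion would
discard most of the panel. A pair of accessions with *no* commonly typed
locus is an error, not a guess.

`upgma()` is written in the package rather than delegated, because the
core-collection algorithm needs the dendrogram's internal structure
(cherries and their heights) and a specified deterministic tie rule: when
several pairs are equally closest, the lowest (row, column) index pair
merges first. Implementation note: merged rows are marked infinite and the
minimum is located with a single column-major `which.min` pass, whose
first-hit semantics are exactly that tie rule. Node heights are half the
merge distance, so the tree is ultrametric with leaf-pair path heights
equal to half the cophenetic distance; `to_newick()` emits branch lengths
as height differences. The implementation is cross-checked in the test
suite against `stats::hclust(method = "average")` and against a naive
oracle that recomputes cluster distances as plain means over the original
pairwise distances.

## Identity cards and marker selection

The coding map is fixed and global: homozygotes A/A…D/D → `1`…`4` (k-th
homozygote → digit k up to nine alleles), the six heterozygotes among
A–D → `A`…`F` in lexicographic pair order, `0` for no band. Beyond four
alleles the map must be extended without disturbing those assignments, so
additional heterozygote pairs are appended after `F` in lexicographic
order (`G`, `H`, …, continuing into lowercase). Encoding and decoding are
exact inverses over the whole 45-state alphabet, which the tests verify
exhaustively.

Marker selection is the greedy PIC-descending rule: sort markers by PIC
(ties broken by input order, for determinism), grow the prefix one marker
at a time, stop when all accession strings are pairwise distinct. Two
accessions identical at every marker are reported as a collision group,
not an error. One subtle choice: string comparison treats `0` as an
ordinary character, so two accessions can be distinguished by *where* they
failed to amplify. The packaged reference cards are consistent with either
treatment; counting `0` as informative is the reading under which a
missing-prone panel can still discriminate, and it is the package's
documented behaviour rather than a claim about any other implementation.

## Stepwise core collections

The stepwise-clustering extractor iterates: (1) allele-sharing distances
on the current set; (2) UPGMA; (3) every cherry — an internal node with two
leaf children, the level at which within-group differences are smallest —
loses one member, chosen uniformly at random; singletons survive the
round; (4) the survivors are re-clustered (each round sees fresh
distances, not a pruned copy of the original tree). Because exact
duplicates sit in cherries at height zero, redundancy is removed first.
The stopping rule is an exact target size, `ceiling(fraction × N)` or an
absolute `size`; when a full round would overshoot the removal quota, only
the lowest cherries (the most redundant pairs) are processed, which lands
the selection exactly on target. An optional guard (`min_na_retention`)
refuses removals that would push mean-Na retention below a floor and stops
early with a warning — useful when aggressively small cores are requested.
All randomness flows from one seed, and the per-round removal log is
returned so a selection can be replayed and audited.

Validation compares the stepwise core against random pseudo-cores of equal
size. Per statistic (Na, Ho, Nei's D, PIC) the per-locus values are the
observations and loci the replicate unit; the package reports a one-way
ANOVA F with its parametric p-value and a distribution-free alternative
that permutes collection labels within each locus block. With few loci and
collections the permutation null is coarse (2 collections × 6 loci admit
only 64 outcomes), so attainable p-values are bounded below — worth
remembering when panels are small.

## The synthetic population generator

The generator exists because validating a core-selection or fingerprinting
procedure needs populations with known structure. Its model: per locus,
ancestral frequencies from a symmetric Dirichlet (concentration 0.5 by
default in the packaged profile); subpopulation frequencies from the
Balding–Nichols distribution Dirichlet$(p\,(1-F_{st})/F_{st})$ — the
"correlated allele frequencies" F-model that STRUCTURE-style analyses
assume; accessions assigned to subpopulations by mixture weights; each
genotype autozygous with probability $F_{is}$ (one allele drawn and
duplicated), otherwise two independent draws; uniform per-cell missingness.
Alleles are relabelled A, B, C, … in decreasing ancestral frequency, so
labels are comparable across loci.

`akebia_profile()` packages the configuration emulating the reference
panel: N = 955 accessions, the observed 28-locus allele-count profile
(19 loci with 4 alleles, 7 with 3, one with 2, one with 5 — 104 alleles),
K = 4 subpopulations with the observed cluster proportions (25.03, 18.32,
17.07, 39.58%), Fst 0.05 (weak structure), Fis 0.48 and an 8% missing
rate. Calibration was done once, analytically plus a 5-seed pilot:
symmetric Dirichlet concentration $\alpha$ gives
$E[\sum p^2] = (\alpha+1)/(k\alpha+1)$, and $\alpha = 0.5$ puts the
allele-count-weighted mean gene diversity near 0.46; within
subpopulations $E[H_O] \approx (1-F_{is})(1-F_{st})\,E[D]$, and
$F_{is} = 0.48$ reproduces the reference heterozygote deficit
(mean Ho ≈ 0.24 against mean D ≈ 0.46). The pilot measured mean Ho
0.240 ± 0.014 and mean D 0.478 ± 0.033 across seeds. These constants are
frozen; they are conditions of the validation, not tuning knobs.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: mutation-model allele spacing (SMM/IAM),
linkage between loci, genotyping error, null alleles masquerading as
homozygotes, and structured missingness. The last point is visible in the
packaged reference cards, where 27% of characters are `0` and the zeros
concentrate in particular markers and accessions; the generator's uniform
8% dropout deliberately models amplification failure as noise, not as the
marker-specific artefact real panels show. Conclusions about discriminating
power under adversarially missing data need real panels.

## Numerical and degenerate-input choices

- Frequency vectors must sum to 1 within 1e−9; distance symmetry within
  1e−12; the $D = 1-1/N_e$ identity is asserted at 1e−12.
- Monomorphic loci: $D = I = PIC = 0$, $N_e = 1$ — ordinary values, not
  errors. An all-missing locus is an error naming the marker.
- Nei's 1972 distance with disjoint allele support returns `Inf`
  explicitly; `upgma()` refuses non-finite input rather than silently
  chaining an infinite merge.
- `Fst = 0` short-circuits to identical subpopulation frequencies (the
  Balding–Nichols scale parameter diverges there).
- Ties: UPGMA merges the lowest index pair; PIC ties keep input marker
  order; all stochastic steps (cherry member choice, pseudo-cores,
  permutations) consume one user-visible seed.

## Problem sizes used in validation

The test suite exercises the full profile scale where the claim depends on
it: the core-vs-random Monte-Carlo comparison runs 20 seeded replicates of
the complete 955 × 28 pipeline (simulate, extract a 164-accession core,
compare to three random cores), and inbreeding recovery uses N = 1000 at
28 loci. Structural and oracle checks run at small n (≤ 7 leaves for tree
oracles, ≤ 6 individuals for brute-force statistics), where exhaustive
verification is feasible. The whole suite completes in about a minute on
one CPU.

## Known limitations

- Diploid, band-scored data only; no polyploids, no fragment-size binning
  from raw capillary traces.
- The greedy marker set is minimal only in the greedy sense; an exact
  minimum-cardinality discriminating set is a set-cover problem the
  package intentionally does not solve.
- No bootstrap support on trees, no neighbor-joining, no
  optimization-based (simulated annealing / M-strategy) core selection.
- F-statistics stop at the simulator's Fis; no Hardy–Weinberg exact tests
  or bootstrap confidence intervals on diversity statistics.
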