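---
title: "Simulation-calibrated detection of admixture between cryptic sympatric species"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-calibrated detection of admixture between cryptic sympatric species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## The problem

Two morphologically cryptic species live in sympatry after secondary
contact and can hybridize in the laboratory.  Has introgression actually
occurred in the field?  Whole-genome resequencing of the two sympatric
species plus an allopatric reference population of one of them gives a
three-population design: an allopatric ingroup `I1`, a sympatric ingroup
`I2`, and the second species as outgroup `O`, related by the species tree
`((I1, I2), O)`.

Formal admixture statistics behave very differently depending on the
direction and strength of gene flow, so `admixscan` first *calibrates* the
detectors on data simulated under the matching demography, then applies
the same code paths to empirical genotype matrices.  Three complementary
detectors are used:

1. **The three-population f3 statistic.**  For a target `C` and sources
   `A`, `B` with sample allele frequencies \(\hat a, \hat b, \hat c\),
   each biallelic site contributes
   \[(\hat c - \hat a)(\hat c - \hat b) - \frac{\hat c (1-\hat c)}{n_C - 1},\]
   the second term being the unbiased correction for sampling error in
   the target frequency.  The genome-wide mean over ascertained sites is
   tested against zero with a delete-one-block weighted jackknife over
   contiguous genomic blocks; a significantly negative value indicates
   the target is a mixture of populations related to the two sources.
2. **Windowed absolute divergence** \(d_{XY}\): the mean per-site
   probability that two alleles, one from each population, differ,
   computed in 50-kb windows.  Gene flow compresses the distribution of
   \(d_{XY}\) between donor and recipient toward zero.
3. **Tree-tip distance proportions.**  For every 50-kb window and a
   quartet of one `I2` tip, one `O` tip and two fixed `I1` tips, an
   unrooted distance tree is built and
   \[\mathrm{Proportion}_{ab} = \frac{d_a}{d_a + d_b},\]
   where \(d_a\) is the patristic distance from the `I2` tip to the `O`
   tip and \(d_b\) the mean patristic distance of the two `I1` tips to
   `O`.  Under the species tree the distribution centres near 0.5;
   introgression from `O` into `I2` shifts windows toward 0, so the lower
   tail of the genome-wide distribution becomes heavier than the upper
   tail.

## The coalescent simulator

`sampleGenealogies()` draws marginal genealogies under a structured
coalescent with time in units of 4N generations, in which a pair of
lineages within a population (all of constant relative size 1) coalesces
at rate 2.  Ingroup lineages merge at 0.4 and the root at 1.5, the
divergence scale matched to the empirical \(d_{XY}\) between the species.
Admixture is a pulse: backwards in time, each lineage in the recipient
population relabels to the donor with probability equal to the pulse
fraction.  Two pulse layouts are available via `pulseSchedule()`: a
single *en masse* event at 0.01, or five events at
0.01, 0.008, 0.006, 0.004, 0.002 representing repeated breakdowns in
assortative mating.  The total fraction \(f\) of the five-event schedule
is split as \(q = 1 - (1-f)^{1/5}\) per pulse, the compound form under
which "total admixture proportion" means the same thing in both layouts
(an `equal` split \(f/5\) is available by argument).

Recombination along the chromosome uses the sequentially Markovian
approximation: breakpoints arrive at rate \(4Nr \times\) (total branch
length), and at each breakpoint a uniformly chosen branch point is
detached and re-coalesced under the same structured process, respecting
each lineage's population membership through pulse and split epochs.  A
faster `blocks` mode draws an independent genealogy per 1-kb block; the
window-averaged statistics used here are insensitive to linkage detail,
and the test suite exercises both modes.  Sequences evolve along each
marginal tree under HKY with the rate matrix normalised to unit mean
rate and branch lengths scaled by 0.01 expected substitutions per site
per 4N unit.  The defaults `kappa = 2` and uniform base frequencies are
package choices, exposed as arguments; the `kappa = 1`/uniform case is
verified against the Jukes-Cantor closed form in the tests and the
transition/transversion split against the K80 closed form.

All randomness flows from one integer seed through two independent
`mt19937_64` streams (genealogies, mutations) with inverse-CDF draws
only, so a model plus seed reproduces haplotypes byte-for-byte on any
platform.

### What the generator does and does not emulate

The generator reproduces the features the detectors are sensitive to:
genealogical discordance along a recombining chromosome, directional
pulse admixture of controlled age and fraction, and finite-sample allele
frequencies at the study's sample sizes (8 haploids per population).  It
does *not* emulate variable population sizes, continuous migration, gene
conversion, mutation-rate heterogeneity, reference-mapping bias, or
genotype-calling error and missingness — empirical missingness enters
only through the VCF path's filters.  Green calibration tests therefore
show the statistics behave correctly under the idealised demography, not
that real data are free of those nuisances.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `samplesPerPopulation` | 8 | haploids | study sample size (24 tips) |
| `splitTimeIngroups` / `splitTimeRoot` | 0.4 / 1.5 | 4N gen | species-tree divergence matched to empirical \(d_{XY}\) |
| pulse times | 0.01 (single); 0.01...0.002 (five) | 4N gen | recent secondary contact |
| `recombinationRate` | 0.001 | 4Nr per bp | population-scaled rate of the study design |
| `chromosomeLength` | 25 Mb | bp | 500 windows of 50 kb |
| `branchScale` | 0.01 | subs/site per 4N | sequence divergence scale |
| window size | 50 kb | bp | the scan resolution (10 kb / 2 kb sliding for follow-up) |
| f3 `blockSize` | 500 kb | bp | 50 jackknife blocks on 25 Mb, comfortably larger than the correlation length |
| `minCallableFrac` | 0.2 | fraction | windows need >20% genotyped sites |

## Numerical and design choices

* **Window coordinates** are 0-based half-open internally and reported as
  1-based inclusive ranges; BED export (`windowsToBed`) is 0-based
  half-open.  Terminal partial windows are kept and flagged.
* **\(d_{XY}\) and \(\pi\)** use full four-allele frequency sums
  (`1 - sum(p_A p_B)`), exact for multiallelic sites; the denominator
  counts sites callable in both populations.  On complete data the
  window value equals all-pairs mismatch averaging exactly, an identity
  the tests assert at `1e-12`.
* **FST** is the Weir–Cockerham weighted windowed estimator
  \(\sum a / \sum (a+b+c)\) over biallelic polymorphic sites, the form
  VCFtools reports; sites with more than two alleles are excluded.  The
  NA gate for a window counts callable (not just polymorphic) sites.
* **Tajima's D** assumes a constant sample size; with ragged missingness
  the constants are computed from the window's modal number of called
  alleles.  This is an approximation: it minimises distortion when
  missingness is mild, and windows dominated by low-coverage sites fail
  the callable gate anyway.
* **Quartet trees** are built from Jukes–Cantor-corrected distances by
  the closed-form least-squares fit of the four-point topology (for four
  taxa this equals neighbor joining, asserted against `ape::nj` in the
  tests).  This replaces per-window maximum-likelihood tree estimation:
  the proportion statistic depends only on patristic distances, and the
  distance fit is deterministic and dependency-free.  Externally
  computed Newick trees can be supplied through `ape` and fed to
  `proportionAB()` for users who prefer ML branch lengths.  Negative
  least-squares branch lengths are clamped to zero; saturated distances
  (mismatch ≥ 0.75) are capped at 5 substitutions/site rather than
  erroring, which keeps degenerate windows flagged but not fatal.
* **IUPAC ambiguity codes** (diploid heterozygotes) contribute the mean
  mismatch over compatible resolutions, e.g. heterozygote versus
  matching homozygote counts 0.5; allele counting gives a diploid call
  two alleles and a haploid call one, so ploidy is invisible to the
  estimators.
* **f3 ascertainment** keeps biallelic sites polymorphic in the union of
  the three populations with at least two called target alleles and no
  minor-allele-frequency filter.  The statistic is unnormalised (no
  heterozygosity denominator), matching the convention of the tooling
  this workflow descends from.  The jackknife is the weighted
  delete-one-block form with per-block site counts.
* **Tie-breaks**: where a reference allele must be chosen from counts
  (FST, f3, VCF export) the alphabetically first observed base is used,
  making every code path deterministic.

## Problem sizes used in tests and acceptance runs

The defaults above describe the full 25-Mb study.  The package's own
test and acceptance runs use 5-Mb chromosomes (100 windows of 50 kb)
with 5–7 replicates per grid cell, and 1–2 Mb for distribution-shape
properties; these sizes give Monte-Carlo error comfortably inside the
asserted tolerances (e.g. the no-admixture mean proportion is asserted
within ±0.02 of 0.5, observed spread across replicates is an order of
magnitude smaller) while keeping a full run in minutes.  The f3
detection threshold is read off the grid `f ∈ {0, 0.05, 0.1, 0.2, 0.3}`
by majority sign over replicates; the expected f3 of the target ordering
crosses zero near `f ≈ 0.13` under this demography, so the grid answer
(20%) is stable at these sizes.

## Known limitations

* The SMC detach–re-coalesce update is the plain Markovian
  approximation; linkage beyond adjacent trees is approximate, which is
  immaterial for window-averaged statistics but would matter for
  LD-based inference (out of scope).
* Tajima's D under heavy, uneven missingness inherits the modal-n
  approximation above.
* The empirical path expects a VCF containing invariant sites with
  per-genotype depth; files without `DP` are rejected rather than
  guessed at.
* f4/D-statistics and f4-ratio estimation are deliberately not
  implemented; with only three populations and no second outgroup they
  are not identifiable in this design.

## A worked run

```{r study, eval = FALSE}
# desk-scale end-to-end study (minutes of CPU):
base <- DemographicModel(chromosomeLength = 5e6)
study <- runSimulationStudy(base, directions = "OtoI2",
                            fractions = c(0, 0.1, 0.2, 0.3),
                            maxCombinations = 16, seed = 1)
print(study)
writeStudyReport(study, "study_report")
```

Per-cell artifacts (window tables, proportion tables, manifest) land in
`study_report/`; the `summary.tsv` row per cell carries the three f3
orderings, mean \(d_{XY}\) per population pair and the mean proportion.
`scripts/acceptance.R` reruns the two headline quantities (the f3
detection threshold and the no-admixture proportion mean) from scratch.
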