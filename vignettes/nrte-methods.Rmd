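---
title: "Detecting non-reference TE insertions and testing for divergent selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-reference TE insertions and testing for divergent selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrte)
library(dplyr)
```

## The problem

Transposable-element (TE) insertions segregate abundantly in plant
panels: a resequenced inbred line often carries tens of thousands of TE
copies absent from the reference assembly. These *non-reference TE*
(NRTE) insertions are biallelic presence/absence variants and can be
treated exactly like any other marker -- they have allele frequencies,
they decay in linkage disequilibrium, they can diverge between
populations under selection, and they can be tested for association with
phenotypes. `nrte` implements a complete desk-scale version of that
programme for a two-population panel of fully inbred lines (temperate
and tropical groups of a maize-like diversity panel): detection of
insertions from short reads, the genome-landscape and
population-genetic summaries such markers support, and a
structure-corrected association scan. A synthetic-data generator with a
recorded truth set makes every stage testable without any external data.

## Split-read junction detection

The detection model is a split-read rule operating on fixed-length
75-bp reads:

1. **Edge database.** Each library TE contributes its terminal 100 bp
   at both ends (`build_edge_db()`); a TE shorter than 200 bp yields
   overlapping edges, and identical edge sequences across family members
   are collapsed with multi-attribution so one read is never credited
   twice.
2. **Quality control.** `qc_reads()` trims trailing low-quality bases,
   drops short reads, and hard-truncates survivors to exactly 75 bp.
3. **Junction rule.** A read is a junction candidate when *k* in
   [20, 55] terminal bases perfectly match the extremity of an edge (the
   prefix of a 5' edge or the suffix of a 3' edge, either strand); the
   complementary 75 - *k* bases (also forced into [20, 55] by the read
   length) are the candidate genomic flank (`match_te_edge()`). The
   20-bp floor makes spurious junctions vanishingly rare: under uniform
   base composition two random flanks share a >20-bp stretch with
   probability `flank_collision_prob(21)` = (1/4)^21 < 4^-20.
4. **Reference-resident filter.** A candidate read whose best
   substitution-only alignment to the reference covers at least 65 read
   bases at 95% identity or better (either strand) derives from a TE
   copy already present in the assembly, not from a new insertion, and
   is discarded (`reference_te_filter()`). Reads spanning a *planted*
   junction cannot trip this filter: their longest contiguous reference
   match is the flank, at most 55 bp.
5. **Flank placement.** The flank must match the reference exactly at
   exactly one location counting both strands (`map_flank()`);
   non-unique or imperfect flanks are dropped. The breakpoint is
   reported as the last reference base before the insertion point, so
   left- and right-junction reads of one insertion agree exactly.
6. **Clustering and genotyping.** Hits within `tolerance_bp` (default
   10 bp) of each other, on one chromosome and in one superfamily class,
   are single-linkage clustered into loci; locus position is the median
   member breakpoint, and a line is a carrier when it contributes at
   least `min_support` hits (default 1). Both knobs are exposed because
   no canonical values exist; 10 bp comfortably absorbs the 1-bp
   left/right ambiguity and small target-site-duplication shifts while
   staying far below the enforced 100-bp spacing of simulated loci.

Exact matching is implemented with 20-bp anchor lookups (the floor of
the junction rule) plus verification, and seed-and-verify placement of
flanks via `Biostrings::matchPDict`; the 65-bp/95% filter is a banded,
substitution-only comparison because the rule is stated as percent
thresholds, not as an aligner's scoring scheme.

## What the simulator emulates -- and what it does not

`simulate_reference()` / `simulate_panel()` build a miniature panel
whose defaults mirror the study conditions the package is aimed at: two
populations of 31 temperate and 52 tropical fully inbred lines (one
haploid donor genome per line), insertion loci divided into
private-temperate, private-tropical and shared classes with Beta
frequency models (low-frequency-dominated spectra, a heavier shared
class), full-length reference-resident TE copies as false-positive bait,
single-end reads at 15x with i.i.d. substitution errors, a genetic map
with a suppressed-recombination middle third, a replicated polygenic
trait (two replicates per line, matching the phenotyping design), and
log-normal expression perturbed multiplicatively in carriers.

Deliberately not modelled: target-site duplications (they shift
breakpoints by a few bp, absorbed by the cluster tolerance), nested or
truncated TEs, TE excision, heterozygosity, indel sequencing errors, and
realistic repeat landscapes. Base composition is uniform i.i.d., which
keeps the 4^-k uniqueness argument exact on synthetic data. Passing
tests therefore demonstrate the pipeline's correctness under clean
split-read conditions -- not its robustness to diverged TE families or
repeat-rich flanks in real genomes.

Truth-set frequencies are *realised* carrier fractions, recorded after
the Bernoulli draws, so downstream frequency checks are exact identities
rather than stochastic comparisons. Reads are deterministic per
(seed, line): FASTQ export and in-memory scanning see identical data.

## Population-genetic methods

**Fst.** No specific estimator is canonical for two-population
presence/absence data over inbred (haploid-equivalent) lines; the
default is Hudson's `1 - Hw/Hb` with sample-size-corrected
within-population heterozygosity, which is well behaved for two
populations and does not degenerate at moderate sample-size imbalance.
Weir-Cockerham theta is available behind `fst_panel(estimator = "wc")`.
Loci monomorphic in both populations are undefined and excluded. The
panel mean is the ratio of sums of the per-locus numerators and
denominators -- the standard bias reduction over averaging per-locus
ratios. The sampling distribution of the mean is obtained by drawing
1000 loci without replacement, 1000 times (`resample_fst()`), and the
99% interval is the empirical 0.5/99.5 percentile range of the
replicate means; the procedure is seed-deterministic.

**Qst.** `trait_qst()` estimates variance components by expected mean
squares from a nested ANOVA: population means over line means give
`MSB`, lines-within-population give `MSL`, and the replicate level gives
`MS_error`. The within-population genetic component removes replicate
noise (`sigma2_GW = MSL - MS_error/r` on line means, harmonic-mean `r`),
the among-population component uses the unbalanced effective size
`n0 = (N - sum(ni^2)/N)/(k-1)`, negative estimates are clamped to zero,
and `Qst = sigma2_GB / (sigma2_GB + 2 sigma2_GW)` -- the haploid-inbred
form in which additive variance enters the denominator twice.
`qst_fst_call()` classifies the selection regime by placing Qst against
the resampled Fst interval: above it, directional selection; below,
stabilizing; within, drift.

With only two populations the between-population mean square has a
single degree of freedom, so a *random* population effect would make the
Qst estimate both noisy and biased; the generator instead applies a
fixed population shift, whose realised among-population component is
`d^2 n1 n2 / (N n0 (k-1))`. At the default shift of 2 with unit line
variance this realises a component ratio of 2.0 on the 31 + 52 panel
(target Qst 0.5), and the mean estimate over 200 simulated panels
recovers it within 0.05.

**LD.** `ld_stats()` computes r² and |D'| from the 2x2 haplotype table
of haploid 0/1 markers, after completeness (`min_geno`, default 0.5) and
monomorphism filters and within a 500-kb pair-distance cap -- the
Haploview-style parameter surface. A Hardy-Weinberg cutoff is accepted
for interface compatibility and ignored with a warning: it has no
meaning for inbred haploid data. |D'| confidence intervals come from a
seeded nonparametric bootstrap over lines (Haploview's likelihood CI
assumes diploid genotypes); `ld_blocks()` then applies the Gabriel rule
with its standard thresholds -- strong LD when the CI is within
[0.70, 0.98+], recombination evidence when the upper bound is below
0.90, and maximal non-overlapping runs in which at least 95% of
informative pairs are strong become blocks, tabulated by size class
including the >= 5 kb count.

## Association

`pca_covariates()` mean-centers the marker matrix without variance
scaling, optionally subsamples columns (seeded) in the spirit of drawing
30,000 SNPs from a much larger set, and fixes component signs by
largest-loading positivity. Three components are used by default -- the
number is not canonical and is config-exposed. `glm_assoc()` fits least
squares of the trait on intercept, covariates and marker; the marker
p-value is the coefficient's t test, computed exactly by partitioned
regression (residualising trait and markers on the covariates once),
which makes a scan over thousands of markers a single matrix operation.
Markers below the MAF floor (default 0.15, inclusive) are excluded;
thresholds come from `bonferroni_threshold(m, alpha)` with the
`alpha = 1` convention (1/48296 = 2.07e-5 for an NRTE scan of that
size; 1/28850 = 3.47e-5 for a transcriptome-wide expression screen).
The windowed re-scan around a candidate gene (`glm_assoc_window()`) is
the same model restricted to markers within +/- 1 Mb, at the looser
p < 0.001 cutoff appropriate to hundreds of tests.
`expression_assoc()` uses Welch's t -- the unequal-variance form is the
safer default when only "t-test" is specified -- and `concordance()`
performs the exact assay-vs-prediction cross-tabulation arithmetic with
one-decimal percentages.

## Numerical and design choices

* **Coordinates** are 1-based inclusive internally (the
  Bioconductor/IRanges convention); BED output is 0-based half-open,
  GFF3/TSV 1-based.
* **Marey interpolation** is piecewise-linear rather than loess/spline:
  it is deterministic, and window rates then integrate back exactly to
  the total interpolated cM span (`sum(rate * width) = cM(end) - cM(0)`,
  checked to 1e-9). Beyond the terminal markers the curve extends with
  the terminal segment's slope.
* **Window densities** normalise by the actual window width so short
  terminal windows are not deflated; gene "density" is a count per Mb
  (the bp-fraction alternative is not used).
* **Gene context** precedence is exon > UTR > intron > 1-kb flank >
  intergenic, strand-aware for the flanks; when a locus sits in two
  genes' flanks the nearer gene wins and exact ties go to upstream.
  Pericentromere boundaries are an input, not inferred.
* **Frequency spectrum bins** are [0, 0.1), [0.1, 0.5], (0.5, 1]; the
  mean frequency is over segregating loci and density is segregating
  loci per Mb.
* **Degenerate inputs**: zero-variance tracks, monomorphic-in-both
  loci, zero genetic variance, empty carrier classes and populations
  with no genotyped lines are all flagged (NA + flag) rather than
  silently coerced to zero; clusters wider than 10x the tolerance are
  split at their largest gap with a warning.
* **Seeds**: every stochastic stage takes an explicit seed; the
  pipeline derives per-stage seeds from one master seed, and RNG state
  is restored after each simulated stage so library calls do not
  perturb user code.

## Problem sizes used in the test-suite experiments

The detection oracle runs on a 2-Mb genome, 20 lines, 100 planted loci
at 15x coverage -- large enough that exact genotype recovery is the
overwhelmingly likely outcome under error-free reads (the expected
number of junction-covering reads per carrier is about 14, so the
chance any carrier lacks support is below 1e-4) while completing in a
few minutes. The estimator experiments use 200 simulated panels
(Qst), 2000 planted loci (Fst resampling), 2000 markers at n = 80
(GLM calibration), 200 replicate panels (power), and 500 windows
(correlation recovery). The power experiment plants an effect of one
replicate-SD and analyses line means of two replicates, matching the
replicated phenotyping design the panel emulates.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, chrom_length = 5e5, n_insertion_loci = 40,
                  n_lines_per_pop = c(temperate = 10, tropical = 12),
                  coverage = 12, error_rate = 0)
ref <- simulate_reference(cfg)
truth <- simulate_panel(cfg, ref)
scan <- scan_simulated_panel(truth, ref)

freqs <- population_frequencies(scan$genotypes, truth$panel)
fst <- fst_panel(scan$genotypes, truth$panel)
fres <- resample_fst(fst, B = 1000, L = 1000, seed = 1)
qst <- trait_qst(simulate_phenotypes(truth), truth$panel)
qst_fst_call(qst, fres)
```

## Known limitations

Absence genotyping is presence-based only: a line with no junction
read is recorded as 0, not missing, matching the presence/absence
treatment of the original analysis but conflating "no insertion" with
"no coverage" at very low depth. Blocks use a simplified Gabriel rule
(no special-casing of short marker runs). The background-recombination
coalescent analysis and multi-population (> 2) Fst are out of scope.
The pipeline detects insertions relative to the reference only; it does
not genotype deletions of reference TE copies.
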