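---
title: "Comparing univariate shape-phenotyping strategies on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing univariate shape-phenotyping strategies on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphogwas)
```

## What this package models

A univariate GWAS of 3D shape needs univariate traits. This package
implements six families of them — inter-landmark distances (`DISTANCE`),
principal component scores (`PCA`), auto-encoder latents (`AE`), and
resemblance scores to random (`RANDOM`), extreme (`EXTREME`) and
syndromic (`SYNDROME`) facial gestalts — together with the scanning,
aggregation, locus-calling and heritability machinery needed to compare
them, and a synthetic-data generator that makes every comparison testable
against a known truth.

The generator is not a fixture: it defines the study conditions. Its
pieces are

* **Genotypes** (`simulate_genotypes`). Diploid allele counts in
  {0, 1, 2}. LD comes from haplotype copying: each block of SNPs carries a
  small pool of founder haplotypes and every individual draws two, so SNPs
  within a block are correlated and blocks are independent. Positions are
  1-based with 5 kb default spacing, which makes the ±250 kb / 1 Mb /
  10 Mb windows of the locus caller meaningful (10,000 SNPs span a 50 Mb
  synthetic chromosome). The `maf` field records the generating pool
  frequency, which lies inside `maf_range` by construction; monomorphic
  realizations are redrawn. Individuals are split into two cohorts
  ("US"/"UK") for the meta-analysis, with the camera covariate tied to the
  cohort.
* **Shapes** (`face_template`, `make_shape_basis`, `simulate_cohort`).
  The template is a bilaterally symmetric half-ellipsoid grid (default
  30 × 21 = 630 vertices, in mm) with a designated 24-landmark subset
  (the first five nasal) and a nose vertex patch. Each cohort shape is
  the template displaced along `K` orthonormal latent directions; the
  latent score of axis `k` is genetic (additive in planted causal allele
  counts, rescaled so the genetic share of the axis variance equals
  `h2_target`), plus covariate terms, plus Gaussian noise. Basis
  directions are mirror-symmetric by default so planted effects survive
  symmetrization — an asymmetric effect direction would be halved by it.
* **Syndromic cohorts** (`simulate_syndromic_groups`): mean-shifted
  clusters along latent axes plus a small control group, mirroring a
  clinical archetype collection.

What the generator does **not** emulate: registration error (shapes are
born in vertex correspondence), population structure beyond independent
ancestry-axis covariates, sex chromosomes, dominance/epistasis, rare
variants, and missing genotypes. Passing tests therefore demonstrate the
correctness and calibration of the analysis machinery under an additive,
well-registered world — not robustness to registration artefacts or
confounding in real cohorts.

## Preprocessing

`gpa_align` runs generalized Procrustes analysis with translation and
rotation only. Scale is deliberately **not** removed: centroid size is
returned and enters the covariate table as "facial size", so size is
adjusted for by regression rather than by superimposition. The consensus
is anchored at the first centred shape and iterated; the Procrustes sum
of squares is non-increasing across iterations (asserted in the tests).
`symmetrize` averages each shape with its reflected-and-relabelled image
(`x` is the lateral axis; the mirror map is an involution fixed by the
template); the construction is idempotent and its output is
mirror-invariant to 1e-10.

`adjust_covariates_pls` residualizes the flattened coordinates on the
covariates by SIMPLS partial least squares. The component count defaults
to the covariate-design rank, in which case the residuals coincide with
ordinary least-squares residuals — the tests pin this limit to an
explicit OLS oracle. The default output is the pure residual field
(column means ≈ 0); the pipeline passes `keep_mean = TRUE` so the
adjusted shapes remain face-like, which matters for the two consumers
that are nonlinear in the coordinates: inter-landmark distances, and the
projection of syndromic faces into the cohort face space.

`segment_hierarchical` groups covarying vertices: similarity between two
vertices is Escoufier's RV coefficient between their `N x 3` coordinate
blocks, and segments come from recursive sign-splits of the Fiedler
vector of the normalized Laplacian. The split is deterministic (the
eigenvector is sign-oriented; near-zero entries join the side of the
first vertex), and labels refine across levels by construction. The
pipeline itself uses the template's nose patch for the nasal segment so
that nasal traits are reproducible across configurations.

## Trait families and their conventions

* `DISTANCE`: all unordered landmark pairs — 276 traits for the
  24-landmark face set, 10 for the 5-landmark nasal set.
* `PCA`: SVD of the centred `N x 3L` matrix; the retained count comes
  from Horn-style parallel analysis (columns permuted independently,
  95th-percentile rule, leading run). Scores are exactly uncorrelated
  in sample, so the family's effective trait count is taken to be the
  trait count without re-estimation.
* `AE`: a fully connected auto-encoder (`3L -> hidden ... -> latent`,
  mirrored decoder; `tanh` hidden layers, linear latent and output)
  trained with mini-batch Adam on reconstruction MSE. The default
  learning rate (3e-3) was set where training is stable across seeds;
  on linear data the reconstruction approaches the PCA optimum (the
  tests bound it at 1.5x the equal-dimension PCA MSE).
* `RANDOM` / `EXTREME` / `SYNDROME`: resemblance scores
  `1 - cos(Mahalanobis angle)` between each individual and a gestalt in
  the parallel-analysis-retained face space. The score keeps the
  "distance" orientation (0 = same direction, 2 = antipodal) and is
  invariant to positive rescaling of either vector; it is undefined for
  a vector exactly at the mean face, which is treated as an error.
  Random gestalts are cohort members drawn without replacement; extreme
  gestalts are the top-k whitened-norm faces (ties broken by index);
  syndromic archetypes are per-group mean projected shapes, kept only if
  a label-permutation test rejects equality with the control mean at
  0.05. The permutation statistic is the whitened norm of
  (archetype − control mean); the test consumes the group member scores
  because the null re-pools and re-averages them.

## GWAS, aggregation, loci

Genotypes are residualized on the covariates once; traits were already
covariate-adjusted during preprocessing and are only centred. Per SNP the
trait is regressed on the residualized genotype; the t statistic uses
`n − 2` degrees of freedom, matching the two-stage adjust-then-regress
design (the difference from the full-model degrees of freedom is
negligible at study sample sizes and the effect estimate itself is
identical to the full multiple-regression coefficient by
Frisch–Waugh–Lovell — the tests assert both). Cohorts are meta-analysed
by fixed-effects inverse-variance weighting.

Within a family, scans combine by per-SNP min-p. The effective trait
count permutes every SNP's genotype once, re-runs the family GWAS, and
sets `Meff = 0.05 / q05(per-SNP null min-p)`. By construction the
group-wide threshold `0.05 / Meff` is the 5th percentile of that null
distribution, i.e. it controls the per-SNP error across the trait family
at 5%; genome-wide control enters through the `5e-8` base level, exactly
as a genome-wide threshold does for a single trait. The calibration
experiments treat it that way: `experiment_meff_calibration` checks the
closed form `0.05 / (1 − 0.95^{1/k})` for independent traits (≈ 9.77 at
k = 10) and `Meff ≈ k` for orthogonal PC scores, and
`experiment_fwer_calibration` verifies the 5% family-wise rate over 400
fresh null SNPs against a correlated trait family.

Locus calling is the three-step procedure: (1) clump every significant
SNP within ±250 kb of the current most significant unassigned SNP, plus
those within 1 Mb at `r² > 0.01` with it; (2) merge loci whose leads are
within 10 Mb and in LD, keeping the lowest-p lead; (3) discard single-SNP
loci. Only SNPs below the threshold participate in clumping (step 1 does
not absorb sub-threshold SNPs), windows are closed intervals in bp, and
LD is the squared allele-count correlation in the panel. Locus sets from
two strategies are matched greedily by ascending lead p with each lead
used once (nearest candidate within 250 kb), giving
`IoU = shared / union`; the greedy-by-significance matching is a design
choice — only the 250 kb criterion itself is canonical.

## Heritability

`ld_scores` computes `l_j = Σ r²_jk` over a position window (self term
included, so `l_j ≥ 1`); no sampling-bias correction is applied, and the
near-constant `(m_window − 1)/n` bias term is absorbed by the regression
intercept, which is left free. `ldsc_regress` fits
`chi² ≈ intercept + slope · l` by weighted least squares (`1/l` weights,
single pass) and reports `h² = slope · M / N` with delete-one
block-jackknife standard errors over ≥ 20 contiguous SNP blocks.

Two numerical choices matter here. First, the heritability experiments
use panels with heterogeneous LD (block lengths 5–50 SNPs, founder pools
of 4–30 haplotypes): with uniform blocks the LD scores are nearly
constant across SNPs and the slope is practically unidentifiable, while
mixed-strength LD — the situation in real genomes — disperses the
regressor. Second, the jackknife SE scales linearly with the residual
chi² noise (asserted directly); note that at fixed sample size it does
not shrink as SNPs are added, because the per-SNP signal `N h² l / M`
falls at the same rate — the estimator gains precision with `N`, not
with `M`.

`compare_h2_groups` runs all pairwise two-tailed t-tests on the per-trait
estimates by category and adjusts them by Benjamini–Hochberg across the
pairwise family; singleton categories are excluded with a warning.

## Study sizes used by the calibration experiments

The experiment drivers fix desk-scale study conditions chosen once:
Meff calibration at `n = 1000`, 10 traits, 10,000 permuted-null SNPs;
family-wise error at 400 fresh null SNPs against a 10-trait family with 5
shared factors; locus recovery with 5 causal SNPs each explaining 5% of
trait variance on an `n = 2000`, `M = 10,000` strong-LD panel (flanking
SNPs must tag the signal or step 3 would discard the peak); heritability
recovery at `n = 2000`, `M = 20,000`, 2,000 causal SNPs, `h² ∈ {0, 0.3,
0.5}`, medians over 10 replicates. The end-to-end `run_pipeline` default
(`n = 400`, `M = 1000`) exercises every stage in seconds; at that scale
individual LD-score heritability estimates are noisy and only the
calibration-scale experiments should be read quantitatively.

## Known limitations

* The auto-encoder is fully connected; mesh-convolutional encoders are an
  extension point, not implemented.
* The LD-score estimator is single-pass weighted (no iterative
  reweighting) and shares the panel between GWAS and LD reference; it is
  intended for ranking and calibration experiments on synthetic data, not
  for numeric compatibility with production LDSC pipelines.
* Resemblance traits inherit the face space: changing the retained
  component count changes the traits. The pipeline ties the count to
  parallel analysis for consistency across families.
* Two-cohort meta-analysis assumes shared true effects across cohorts
  (fixed effects); cohort heterogeneity is not modelled.
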