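---
title: "ROI texture radiomics: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI texture radiomics: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roitexture)
```

## The analysis this package implements

`roitexture` quantifies image texture inside segmented regions of interest
(ROIs) of 3D intensity volumes — the motivating application is hippocampus
and amygdala ROIs in T1-weighted MRI of a two-group case-control cohort —
and carries the features through a complete statistical and machine-learning
workflow:

1. **Quantization.** In-mask intensities are equalized to `Ng = 32` grey
   levels by rank-based binning.
2. **GLCM counting.** For every 2D slice containing the region, one
   grey-level co-occurrence matrix per direction
   $\theta \in \{0°, 45°, 90°, 135°\}$ at pixel offset $d = 1$:
   $P_{d,\theta}(i,j)$ counts ordered in-mask pixel pairs with levels
   $(i, j)$ at the displacement for $(d, \theta)$.
3. **Quantifiers.** Eleven Haralick-type scalar descriptors per normalized
   GLCM (energy, entropy, correlation, contrast, homogeneity, variance,
   sum-mean, cluster shade, cluster tendency, maximum probability, inverse
   variance), averaged feature-wise over all (slice, direction) pairs to
   one 11-vector per region per subject.
4. **Group statistics.** Per-feature two-group ANOVA with Holm–Bonferroni
   control across the region's 11 tests; per-class mean ± SD summaries;
   Dice overlap between rater masks.
5. **Classification.** RBF-kernel SVM ($k(x,y) = e^{-\gamma\|x-y\|^2}$,
   $\gamma = 1$, $C = 1$) with leave-one-out cross-validation and z-score
   normalization (Eq. `(x - \bar x)/\sigma`, sample SD) fitted on each
   training fold; accuracy/sensitivity/specificity from the confusion
   counts with class 1 (the control group) positive; stratified 10-fold
   mean ROC AUC from the SVM decision values.
6. **Calibration and importance.** A label-permutation null distribution of
   the LOOCV accuracy with empirical $p = (1 + \#\{null \ge obs\})/(n+1)$,
   and a 1000-tree random forest whose root-node split frequencies (plus
   out-of-bag permutation importance) rank the features.

Because the original cohort is not redistributable, a synthetic-cohort
generator stands in for the imaging data. It is first-class, tested code:
every downstream stage is exercised end to end against it.

## The synthetic cohort model

Each subject's volume is a Gaussian random field: white noise smoothed by a
separable Gaussian kernel whose SD is the subject's **correlation length**
(in voxels), then standardized over the in-mask voxels and mapped to
`mean_intensity` + `noise_sd` × field. Standardizing within the mask makes
every subject's masked intensity histogram share its mean and SD *exactly*;
class differences live only in spatial structure, mirroring the observation
that case and control intensity histograms are nearly identical while their
textures differ. Because quantization is rank-based, texture features are
invariant under any strictly monotone intensity transform, so `noise_sd`
and `mean_intensity` are cosmetic; the correlation length is the one
texture knob, and it moves GLCM contrast and correlation in opposite
directions (shorter correlation length ⇒ rougher texture ⇒ higher contrast,
lower correlation).

The ROI is an axis-aligned ellipsoid (default semi-axes 12 × 10 × 9 voxels
in a 40³ grid, ≈ 3300 voxels — hippocampal scale at coarse resolution,
large enough for stable GLCMs while keeping a full cohort simulation near
one second). A second rater's mask is produced by flipping each
boundary-adjacent voxel with probability `mask_error_rate` (default 0.1),
concentrating disagreement at structure borders as real raters do; the
resulting Dice overlap (≈ 0.95) is at the optimistic end of published
inter-rater agreement for small structures.

**Age-matched pairing.** The default cohort mirrors an age-matched
case-control design of 14 + 14 children (a 20 + 16 variant reproduces the
imbalanced group): each case shares one age (uniform on 4–15 years) with
its matched control, and the correlation length is
`class base + age_slope × (age − mid) + N(0, cl_jitter)` with defaults
`age_slope = 0.12` per year and `cl_jitter = 0.08`. Texture smoothens with
development, so age acts as a strong latent factor *shared within pairs*.
This matters beyond realism: matched partners end up close in feature
space, which is what makes the classifier's chance-level behaviour
calibrate correctly (next section).

Default class texture: correlation lengths 1.5 (class 0) vs 4.0 (class 1),
a strongly separable condition; setting both classes to the same value
gives the uninformative condition.

`simulate_feature_table()` bypasses imaging and draws each feature
independently from a per-class normal location-scale model — appropriate
for calibrating the ANOVA/Holm stage (type-I error, power) and the forest
importance, where feature covariance is irrelevant.
`simulate_matched_table()` instead draws 14 matched pairs sharing two
pair-level latent factors that load on all 11 features with mixed signs
(smoothness-type quantifiers move opposite to heterogeneity-type ones) plus
small idiosyncratic noise; it reproduces the feature-space geometry of a
matched cohort and is the right input for classifier null calibration.

## Chance-level calibration of the leave-one-out SVM

A subtlety of this pipeline deserves a frank account. After z-scoring, any
set of 11 unit-variance feature columns has mean squared pairwise distance
$E\|x-y\|^2 = 22$ between independent subjects. With $\gamma = 1$ the RBF
kernel $e^{-22} \approx 0$: for feature tables with *independent* columns
the Gram matrix is nearly diagonal, the SVM's decision reduces to its
intercept — the majority class of the training fold — and under
leave-one-out that majority is always the *opposite* of the held-out
subject's class (13 vs 14). The permutation-null accuracy of such a table
collapses toward 0%, not 50%.

Real cohorts do not behave like this because their feature vectors are
strongly correlated across subjects: a dominant latent factor (development)
places subjects on a low-dimensional manifold with close neighbours, and a
matched design guarantees each subject one near neighbour — its partner.
In that regime the held-out decision is dominated by the nearest
neighbour's label and the null calibrates near chance. There is a hard
ceiling: for a balanced $n + n$ cohort, any classifier that "copies" local
training labels has permutation-null mean accuracy at most
$(n-1)/(2n-1) = 13/27 \approx 48.1\%$, because the held-out subject's class
is underrepresented by one in its training fold. The matched-table null in
this package measures mean ≈ 46–49% and median within one accuracy quantum
($100/28 \approx 3.6$ points) of 50% — as close to the analytic 50% chance
level as the estimator permits. The same leave-one-out pessimism explains
why image-derived *uninformative* cohorts score below 50% on their observed
accuracy; the honest test of "indistinguishable from chance" is therefore
whether the observed accuracy falls inside the central band of its own
permutation null, which is what the test suite asserts.

## Numerical and convention choices

* **Quantifier formulas.** Fixed as in `?haralick_features`, with levels
  0-based (`0..Ng−1`); entropy uses log base 2; correlation is defined 0
  when a marginal SD vanishes; variance uses the grand mean
  $\mu = \sum (i+j)/2 \; p(i,j)$ (the sum-mean); `0·log 0 := 0`. A 1-based
  level convention would shift sum-mean by 1 and variance-type features by
  a constant; the 0-based choice is stated rather than argued.
* **Equalization.** Rank-based equal-count binning over in-mask voxels,
  intensity ties broken by voxel storage order; a constant region maps to
  level 0. Uniform-width binning is available as `bin_mode = "uniform"`.
* **GLCMs are unsymmetrized by default** (ordered pairs; the reversed
  displacement gives the transpose), with `symmetrize = TRUE` available.
  Quantifier-then-average: quantifiers are applied per GLCM and the 11
  features averaged across all valid (slice, direction) pairs; GLCMs with
  no valid pair (thin slices) are skipped, never imputed as zeros.
* **Slicing plane** defaults to the first axis (sagittal, matching
  slice-by-slice manual segmentation practice); configurable.
* **Offsets** $d \in \{2, 3, 4\}$ are implemented and tested but excluded
  from the default pipeline, which uses $d = 1$.
* **Z-scoring** uses the sample SD ($n-1$). For cross-validation the
  statistics are fitted on each training fold only (no leakage);
  `normalize = "global"` reproduces whole-table normalization for
  comparison.
* **ANOVA edge cases.** Zero within-group variance with equal means gives
  $F = 0, p = 1$; with unequal means $F = \infty, p = 0$.
* **SVM ties.** A decision value of exactly 0 predicts the negative class —
  deterministic and documented.
* **Metric printing** truncates (not rounds) to two decimals, so
  $19/28 = 67.857\%$ prints as `67.85`; full-precision values are kept in
  all JSON artifacts.
* **Holm correction** is applied within each region's 11 tests, not across
  regions.
* **Forest defaults.** 1000 trees, with-replacement bootstrap of the n
  subjects, $\sqrt{p}$ candidate features per node, majority-vote leaves,
  no depth limit (the conventional bagging configuration). Root-node counts
  always sum to the number of trees. Conditional on a single realized null
  table the root splits concentrate on whichever features happen to look
  informative in that sample; uniformity of root choice under the null is a
  property *across* datasets, and the tests assert it that way.

## Problem sizes used by the tests

The suite runs entirely on synthetic data built at test time: grids up to
16 × 16 for the exhaustive GLCM oracles, 50 random 8 × 8 matrices for the
quantifier oracle, 200 random group pairs for the ANOVA oracle, 200 seeds
for the Holm power study, 300 permutation trials (one 14 + 14 matched
table) for null calibration, and two 28-subject image cohorts at 40³ voxels
for the end-to-end checks. The acceptance script runs 600 label
permutations of the full LOOCV pipeline on one matched table.

## What passing these tests does and does not show

The generator validates the *mechanics* and *calibration* of the pipeline:
counting is exact, quantifiers match independent oracles, error rates are
controlled, the classifier separates what is separable and is honest about
chance. It does not claim anatomical realism: there are no bias fields, no
partial-volume tissue mixtures, no scanner/site effects, no real
neuroanatomy, and the correlation-length mechanism is a stand-in for
whatever drives group texture differences in real brains — not a biological
claim. Conclusions about real cohorts still require real data.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(cohort = cohort_spec(seed = 1), seed = 1,
                       n_trials = 200, n_trees = 1000)
res <- run_pipeline(cfg, "run1")
res$classification     # confusion counts + truncated metrics
res$permutation        # null mean/SD/median, empirical p
head(res$group_stats)  # per-feature mean±SD, F, p, Holm flag
```
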