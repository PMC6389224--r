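# roitexture

Texture radiomics for masked regions of interest in 3D intensity volumes,
with the downstream statistics and classification needed for a two-group
case-control study. The motivating application is grey-level co-occurrence
matrix (GLCM) analysis of manually segmented hippocampus/amygdala regions
in T1-weighted MRI of autism-spectrum versus typically developing children,
but every stage is generic: any volume + binary mask + binary label fits.

The package is aimed at researchers who want a small, fully testable,
end-to-end radiomics pipeline: quantization → GLCM → Haralick quantifiers →
group tests → SVM cross-validation → permutation calibration → feature
importance, plus a synthetic-cohort generator so that all of it runs and
validates without access to clinical data.

## The model in brief

For a 2D slice `I` of a quantized region, the co-occurrence matrix at
offset `d` and direction `θ` counts ordered in-mask pixel pairs:

    P_{d,θ}(i,j) = #{ p : I(p) = i, I(p + (dx,dy)) = j, p and p+(dx,dy) in mask }

with `(dx,dy)` the displacement for `(d,θ)`. In-mask intensities are first
rank-equalized to `Ng = 32` grey levels; per slice, four GLCMs are computed
(`d = 1`, `θ ∈ {0°, 45°, 90°, 135°}`), each normalized to a probability
matrix `p(i,j)` and summarized by eleven quantifiers — energy `Σp²`,
entropy `−Σ p log₂ p`, correlation, contrast `Σ(i−j)²p`, homogeneity,
variance, sum-mean, cluster shade, cluster tendency, maximum probability,
inverse variance — then averaged feature-wise over all slices and
directions into one 11-vector per region per subject.

Features are z-scored (`x_norm = (x − x̄)/σ`) and tested per feature with
two-group ANOVA under Holm–Bonferroni control (11 tests per region).
Classification uses an RBF-kernel SVM (`γ = 1`, `C = 1`) under
leave-one-out cross-validation, reporting accuracy, sensitivity and
specificity from the confusion counts (controls are the positive class)
and a stratified 10-fold mean ROC AUC. Chance level is calibrated by
re-running the full LOOCV under label permutations; feature importance
comes from the root-node split frequencies of a 1000-tree random forest.

## Worked example

```r
library(roitexture)

spec    <- cohort_spec(seed = 1)            # 14 + 14 age-matched synthetic cohort
cohort  <- simulate_cohort(spec)            # volumes + rater masks + labels
features <- extract_cohort_features(cohort) # 28 x 11 GLCM feature table

loocv_svm(features)
#> SVM classification report (class 1 positive)
#>   confusion: TP=14 TN=8 FP=6 FN=0
#>   accuracy 78.57%  sensitivity 100.00%  specificity 57.14%

gs <- group_summary(features)
gs[gs$significant, c("feature", "p")]       # 9 of 11 features survive Holm
#>             feature        p
#> 1            energy 1.86e-06
#> 2           entropy 1.21e-11
#> 3       correlation 4.16e-07
#> 4          contrast 1.32e-07
#> ...

sort(rf_root_importance(features, seed = 1)$root_counts, decreasing = TRUE)[1:3]
#>      correlation inverse_variance         contrast
#>              204              198              183

permutation_test(features, n_trials = 200, seed = 2)
#> Permutation null of LOOCV accuracy
#>   200 trials: 30.54 +/- 14.85 %, median 28.57 %
#>   observed 78.57 %, empirical p = 0.004975
```

The two synthetic classes differ only in the spatial correlation length of
their masked texture (1.5 vs 4.0 voxels) — their intensity histograms are
identical by construction — yet the classifier separates them far above its
permutation null (p ≈ 0.005), the Holm-corrected ANOVA flags most
quantifiers, and GLCM correlation tops the forest's root-node ranking.
`run_pipeline(pipeline_config(...), "out_dir")` performs all of the above
plus k-fold AUC in one call, writing per-stage CSV/JSON artifacts, and
`inst/cli/roitexture` exposes each stage as a shell subcommand.

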