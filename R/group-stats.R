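#' Z-score normalize a feature table
#'
#' Centers and scales each feature column, `x_norm = (x - mean) / sd`, with
#' sample SD (n - 1 denominator). When `reference` is given, the statistics
#' are fitted on those rows only and applied to every row — the pattern used
#' to normalize a held-out subject with training-fold statistics and avoid
#' information leakage.
#'
#' @param table A [feature_table()].
#' @param reference Optional integer indices of the reference (training)
#'   rows; default all rows.
#' @return A [feature_table()] with normalized feature columns.
#' @export
zscore_normalize <- function(table, reference = NULL) {
  m <- feature_matrix(table)
  ref <- if (is.null(reference)) seq_len(nrow(m)) else as.integer(reference)
  mu <- colMeans(m[ref, , drop = FALSE])
  sd <- apply(m[ref, , drop = FALSE], 2, stats::sd)
  if (any(sd == 0)) {
    stop("zero-variance feature on the reference subset: ",
         paste(names(sd)[sd == 0], collapse = ", "))
  }
  z <- sweep(sweep(m, 2, mu), 2, sd, `/`)
  feature_table(z, table$label, table$subject_id)
}

#' One-way two-group ANOVA
#'
#' Fixed-effects F test of equal group means, `F ~ F(1, n - 2)`. For two
#' groups this is exactly the square of the pooled-variance t statistic.
#' Degenerate input with zero within-group variance and equal means returns
#' `F = 0, p = 1`; zero within-group variance with differing means returns
#' `F = Inf, p = 0`.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @return Named list with `F` and `p`.
#' @export
anova_two_group <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  na <- length(values_a); nb <- length(values_b); n <- na + nb
  ssw <- sum((values_a - mean(values_a))^2) + sum((values_b - mean(values_b))^2)
  if (ssw == 0) {
    if (mean(values_a) == mean(values_b)) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  gm <- (na * mean(values_a) + nb * mean(values_b)) / n
  ssb <- na * (mean(values_a) - gm)^2 + nb * (mean(values_b) - gm)^2
  f <- (ssb / 1) / (ssw / (n - 2))
  list(F = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

#' Holm-Bonferroni step-down rejections
#'
#' Family-wise error control by the standard step-down rule: sort p values
#' ascending and reject while `p_(k) <= alpha / (m - k + 1)`, stopping at
#' the first failure. Uniformly more powerful than plain Bonferroni.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @param alpha Significance level (default 0.05).
#' @return Logical rejection flags, same order as `pvals`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stop("p values must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stats::p.adjust(pvals, method = "holm") <= alpha
}

#' Per-feature two-group summary with multiplicity control
#'
#' For each of the 11 features: per-class mean and sample SD, the two-group
#' ANOVA F and p, and the Holm-Bonferroni rejection flag at level `alpha`
#' applied across the 11 tests of this table (one region = one family).
#'
#' @param table A [feature_table()] with >= 2 subjects per class.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `group_test_result`: data frame with one row per feature and
#'   columns `feature`, `mean_class0`, `sd_class0`, `mean_class1`,
#'   `sd_class1`, `F`, `p`, `significant`.
#' @export
group_summary <- function(table, alpha = 0.05) {
  assert_two_classes(table)
  m <- feature_matrix(table)
  a <- m[table$label == 0L, , drop = FALSE]
  b <- m[table$label == 1L, , drop = FALSE]
  tests <- lapply(texture_feature_names(), function(f) {
    r <- anova_two_group(a[, f], b[, f])
    data.frame(feature = f,
               mean_class0 = mean(a[, f]), sd_class0 = stats::sd(a[, f]),
               mean_class1 = mean(b[, f]), sd_class1 = stats::sd(b[, f]),
               F = r$F, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tests)
  out$significant <- holm_bonferroni(out$p, alpha = alpha)
  class(out) <- c("group_test_result", "data.frame")
  out
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: the standard overlap agreement between
#' two segmentations of the same grid.
#'
#' @param mask_a,mask_b Binary arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("masks must have the same shape")
  }
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) stop("both masks are empty; Dice undefined")
  2 * sum(a & b) / (sa + sb)
}
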