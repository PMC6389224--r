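test_that("metric arithmetic reproduces the confusion-count worked examples", {
  # balanced group: 10/14 negatives and 9/14 positives correct
  m <- compute_metrics(TP = 9, FN = 5, TN = 10, FP = 4)
  expect_equal(m$accuracy, 100 * 19 / 28)
  expect_equal(unname(m$printed),
               c("67.85", "64.28", "71.42"))

  # imbalanced group: 17/20 negatives and 10/16 positives correct
  m2 <- compute_metrics(TP = 10, FN = 6, TN = 17, FP = 3)
  expect_equal(unname(m2$printed), c("75.00", "62.50", "85.00"))
  expect_equal(m2$sensitivity, 62.5)
  expect_equal(m2$specificity, 85)

  m3 <- compute_metrics(TP = 5, TN = 5, FP = 0, FN = 0)
  expect_equal(c(m3$accuracy, m3$sensitivity, m3$specificity), c(100, 100, 100))

  expect_error(compute_metrics(0, 5, 5, 0), "positive")
  expect_error(compute_metrics(5, 0, 0, 5), "negative")
})

test_that("printed metrics truncate rather than round", {
  # 19/28 = 67.857...% must print 67.85, not 67.86
  expect_equal(unname(truncate2 <- roitexture:::truncate2(100 * 19 / 28)), "67.85")
  expect_equal(roitexture:::truncate2(99.999), "99.99")
})

test_that("LOOCV SVM separates well-separated clusters and is duplication-invariant", {
  set.seed(31)
  m <- matrix(rnorm(28 * 11), 28, 11)
  m[15:28, ] <- m[15:28, ] + 10   # inter-class distance ~10 SD
  colnames(m) <- texture_feature_names()
  tab <- feature_table(m, rep(c(0L, 1L), each = 14))
  r <- loocv_svm(tab)
  expect_equal(r$accuracy, 100)
  expect_equal(r$TP + r$TN + r$FP + r$FN, 28L)

  # duplicating every subject preserves confusion proportions
  tab2 <- feature_table(rbind(m, m), rep(rep(c(0L, 1L), each = 14), 2),
                        subject_ids = sprintf("D%03d", 1:56))
  r2 <- loocv_svm(tab2)
  expect_equal(r2$accuracy, r$accuracy)
  expect_equal(c(r2$TP, r2$TN, r2$FP, r2$FN) / 2, c(r$TP, r$TN, r$FP, r$FN))

  expect_error(loocv_svm(feature_table(m[1:3, ], c(0L, 0L, 1L))), "at least 2")
})

test_that("trapezoidal AUC matches pROC and is rank-invariant", {
  set.seed(4)
  for (rep in 1:20) {
    sc <- rnorm(30); y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    mine <- roitexture:::trapezoid_auc(sc, y)
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(mine, ref, tolerance = 1e-12)
    # invariance under strictly monotone transforms of the scores
    expect_equal(roitexture:::trapezoid_auc(exp(sc), y), mine, tolerance = 1e-12)
  }
})

test_that("k-fold AUC is 1 for separable data and ~0.5 under permuted labels", {
  set.seed(55)
  m <- matrix(rnorm(28 * 11), 28, 11); m[15:28, ] <- m[15:28, ] + 10
  colnames(m) <- texture_feature_names()
  tab <- feature_table(m, rep(c(0L, 1L), each = 14))
  a <- kfold_auc(tab, k = 10, seed = 1)
  expect_equal(a$mean_auc, 1)

  # permuted labels: mean AUC within Monte-Carlo error of 0.5 over 40 seeds
  tabm <- simulate_matched_table(seed = 6)
  aucs <- vapply(1:40, function(s) {
    tp <- tabm; set.seed(s); tp$label <- sample(tp$label)
    kfold_auc(tp, k = 7, seed = s)$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 3 * stats::sd(aucs) / sqrt(length(aucs)))

  expect_error(kfold_auc(tab, k = 1), "k must be")
})

test_that("permutation test is seeded, calibrated, and powerful on real signal", {
  tabm <- simulate_matched_table(seed = 8)
  p1 <- permutation_test(tabm, n_trials = 120, seed = 10)
  p2 <- permutation_test(tabm, n_trials = 120, seed = 10)
  expect_identical(p1$trials, p2$trials)
  expect_equal(length(p1$trials), 120L)
  expect_true(p1$p > 0 && p1$p <= 1)

  # informative table: tiny empirical p
  tabs <- simulate_matched_table(class_shift = c(3, rep(0, 10)), seed = 8)
  ps <- permutation_test(tabs, n_trials = 120, seed = 10)
  expect_lte(ps$p, 0.01)
  expect_gt(ps$observed, ps$median)

  expect_error(permutation_test(tabm, n_trials = 50), "n_trials")
})

test_that("random-forest root counts are conserved and identify the dominant feature", {
  shift <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 4, 0)  # max_probability separates classes
  top_ok <- vapply(1:10, function(s) {
    tab <- simulate_feature_table(14, 14, means_class1 = shift, seed = s)
    imp <- rf_root_importance(tab, n_trees = 300, seed = s)
    expect_equal(sum(imp$root_counts), 300L)
    names(which.max(imp$root_counts)) == "max_probability" &&
      names(which.max(imp$oob_importance)) == "max_probability"
  }, logical(1))
  # both importance measures agree on the informative feature
  expect_gte(mean(top_ok), 0.9)

  # all-noise features: no feature is systematically preferred at the root.
  # Conditional on one realized table the forest concentrates on whichever
  # features happen to look informative there, so uniformity is assessed
  # across independent null tables: pooled shares stay near 1/11 and the
  # per-table winner varies.
  imps <- lapply(1:12, function(s) {
    rf_root_importance(simulate_feature_table(14, 14, seed = 300 + s),
                       n_trees = 250, seed = s)$root_counts
  })
  pooled <- Reduce(`+`, imps)
  expect_equal(sum(pooled), 12L * 250L)
  shares <- pooled / sum(pooled)
  expect_true(all(shares > 1 / 33 & shares < 3 / 11))
  winners <- vapply(imps, function(x) names(which.max(x)), character(1))
  expect_gte(length(unique(winners)), 4L)
})
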