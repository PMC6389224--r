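#' Classification metrics from confusion counts
#'
#' Accuracy = (TP + TN) / (TP + FP + TN + FN), sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), all as percentages. Class 1 (the control
#' group by convention) is positive. Printed values truncate — not round —
#' to two decimals, so 19/28 prints as 67.85; full-precision values are kept
#' alongside.
#'
#' @param TP,TN,FP,FN Non-negative confusion counts.
#' @return Named list with `accuracy`, `sensitivity`, `specificity` (%),
#'   and `printed`, a named character vector of the 2-decimal truncations.
#' @export
compute_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (TP + FN == 0) stop("no positive examples: sensitivity undefined")
  if (TN + FP == 0) stop("no negative examples: specificity undefined")
  acc <- 100 * (TP + TN) / (TP + FP + TN + FN)
  sens <- 100 * TP / (TP + FN)
  spec <- 100 * TN / (TN + FP)
  printed <- vapply(c(accuracy = acc, sensitivity = sens, specificity = spec),
                    truncate2, character(1))
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       printed = printed)
}

truncate2 <- function(x) sprintf("%.2f", floor(x * 100) / 100)

# Fit an RBF SVM on rows `train` of the z-scored matrix and return the
# decision value for rows `test`, oriented so positive favors class 1.
svm_decision <- function(x_train, y_train, x_test, C, gamma) {
  y <- factor(y_train, levels = c(0L, 1L))
  fit <- e1071::svm(x_train, y, kernel = "radial", gamma = gamma, cost = C,
                    scale = FALSE)
  pr <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071 names the column "<first>/<second>"; positive decision values favor
  # the first-named class. Flip so positive always favors class "1".
  if (colnames(dv)[1] == "0/1") dv <- -dv
  as.numeric(dv)
}

# z-score columns of m using statistics of the rows `ref`; constant columns
# on the reference get scale 1 (they carry no information either way).
zscore_by_ref <- function(m, ref) {
  mu <- colMeans(m[ref, , drop = FALSE])
  sd <- apply(m[ref, , drop = FALSE], 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(m, 2, mu), 2, sd, `/`)
}

#' Leave-one-out SVM classification
#'
#' For each subject: z-score all features with the statistics of the
#' remaining subjects, train an RBF-kernel SVM (`k(x,y) = exp(-gamma
#' ||x-y||^2)`) on them, and predict the held-out subject from the sign of
#' the decision value (a value of exactly 0 predicts negative). Confusion
#' counts accumulate with class 1 positive.
#'
#' @param table A [feature_table()] with >= 2 subjects per class.
#' @param C SVM cost parameter (default 1).
#' @param gamma RBF kernel width parameter (default 1).
#' @param normalize `"fold"` (default) fits z-score statistics on each
#'   training fold only; `"global"` normalizes the whole table once before
#'   cross-validation (kept for comparison with whole-cohort normalization).
#' @return A `classification_report`: list with `TP`, `TN`, `FP`, `FN`,
#'   `accuracy`, `sensitivity`, `specificity` (%), `printed`, `predictions`
#'   (per-subject 0/1), and empty AUC fields (see [kfold_auc()]).
#' @export
loocv_svm <- function(table, C = 1, gamma = 1,
                      normalize = c("fold", "global")) {
  normalize <- match.arg(normalize)
  assert_two_classes(table)
  m <- feature_matrix(table)
  y <- table$label
  n <- nrow(m)
  if (normalize == "global") m <- zscore_by_ref(m, seq_len(n))
  pred <- integer(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    xm <- if (normalize == "fold") zscore_by_ref(m, tr) else m
    dv <- svm_decision(xm[tr, , drop = FALSE], y[tr], xm[i, , drop = FALSE],
                       C = C, gamma = gamma)
    pred[i] <- as.integer(dv > 0)
  }
  report_from_predictions(y, pred)
}

report_from_predictions <- function(y, pred) {
  TP <- sum(y == 1L & pred == 1L); TN <- sum(y == 0L & pred == 0L)
  FP <- sum(y == 0L & pred == 1L); FN <- sum(y == 1L & pred == 0L)
  met <- compute_metrics(TP, TN, FP, FN)
  structure(c(list(TP = TP, TN = TN, FP = FP, FN = FN), met,
              list(predictions = pred, fold_auc = numeric(0),
                   mean_auc = NA_real_)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("SVM classification report (class 1 positive)\n")
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  accuracy %s%%  sensitivity %s%%  specificity %s%%\n",
              x$printed["accuracy"], x$printed["sensitivity"],
              x$printed["specificity"]))
  if (length(x$fold_auc)) {
    cat(sprintf("  mean AUC over %d folds: %.4f\n", length(x$fold_auc),
                x$mean_auc))
  }
  invisible(x)
}

# Trapezoidal ROC AUC from decision scores (ties contribute 1/2); this is
# the Mann-Whitney statistic of scores of positives vs negatives.
trapezoid_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(neg, pos))
  (sum(r[seq_along(pos) + length(neg)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Seeded stratified fold assignment: each class's indices are shuffled and
# dealt round-robin into k folds.
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' k-fold cross-validated ROC AUC
#'
#' Splits subjects into `k` seeded stratified folds; each fold in turn is
#' held out, the SVM is trained on the rest (with fold-local z-scoring),
#' and the held-out subjects' continuous decision values give that fold's
#' trapezoidal ROC AUC. Folds whose test set contains a single class yield
#' no AUC and are skipped.
#'
#' @inheritParams loocv_svm
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List with `fold_auc` (per usable fold) and `mean_auc`.
#' @export
kfold_auc <- function(table, k = 10L, seed = 1L, C = 1, gamma = 1,
                      normalize = c("fold", "global")) {
  normalize <- match.arg(normalize)
  if (k < 2L) stop("k must be >= 2")
  assert_two_classes(table)
  m <- feature_matrix(table)
  y <- table$label
  if (normalize == "global") m <- zscore_by_ref(m, seq_len(nrow(m)))
  fold <- stratified_folds(y, k, seed = seed)
  aucs <- c()
  for (f in sort(unique(fold))) {
    te <- which(fold == f); tr <- which(fold != f)
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) next
    xm <- if (normalize == "fold") zscore_by_ref(m, tr) else m
    dv <- svm_decision(xm[tr, , drop = FALSE], y[tr],
                       xm[te, , drop = FALSE], C = C, gamma = gamma)
    a <- trapezoid_auc(dv, y[te])
    if (!is.na(a)) aucs <- c(aucs, a)
  }
  if (length(aucs) == 0L) stop("no fold produced a two-class test set; reduce k")
  list(fold_auc = aucs, mean_auc = mean(aucs))
}

#' Label-permutation null distribution of LOOCV accuracy
#'
#' Builds the empirical null of classifier accuracy by re-running the full
#' leave-one-out SVM pipeline under randomly permuted labels, which renders
#' them information-less. The observed (true-label) accuracy is compared to
#' the null tail: `p = (1 + #{null >= observed}) / (n_trials + 1)`.
#'
#' @inheritParams loocv_svm
#' @param n_trials Number of permutation trials (>= 100; default 1000).
#' @param seed RNG seed for the permutations.
#' @return A `permutation_null`: list with `trials` (null accuracies, %),
#'   `mean`, `sd`, `median`, `observed` (accuracy on true labels), `p`,
#'   `n_trials` and `seed`.
#' @export
permutation_test <- function(table, n_trials = 1000L, seed = 1L,
                             C = 1, gamma = 1,
                             normalize = c("fold", "global")) {
  normalize <- match.arg(normalize)
  n_trials <- as.integer(n_trials)
  if (n_trials < 100L) stop("n_trials must be >= 100 for a usable null")
  observed <- loocv_svm(table, C = C, gamma = gamma,
                        normalize = normalize)$accuracy
  set.seed(seed)
  trials <- vapply(seq_len(n_trials), function(t) {
    tab <- table
    tab$label <- sample(tab$label)
    loocv_svm(tab, C = C, gamma = gamma, normalize = normalize)$accuracy
  }, numeric(1))
  structure(list(trials = trials, mean = mean(trials),
                 sd = stats::sd(trials), median = stats::median(trials),
                 observed = observed,
                 p = (1 + sum(trials >= observed)) / (n_trials + 1),
                 n_trials = n_trials, seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null of LOOCV accuracy\n")
  cat(sprintf("  %d trials: %.2f +/- %.2f %%, median %.2f %%\n",
              x$n_trials, x$mean, x$sd, x$median))
  cat(sprintf("  observed %.2f %%, empirical p = %.4g\n", x$observed, x$p))
  invisible(x)
}

#' Random-forest feature importance by root-node frequency
#'
#' Grows a bagged random forest (with-replacement bootstrap, sqrt(p)
#' candidate features per node) and counts, for each feature, how many
#' trees chose it for their root split — the most group-informative
#' features appear there. Out-of-bag permutation importance (mean decrease
#' in accuracy) is reported alongside; the two measures tend to agree on
#' the dominant feature.
#'
#' @param table A [feature_table()].
#' @param n_trees Number of trees (default 1000).
#' @param seed RNG seed.
#' @return An `importance_report`: list with `root_counts` (named, sums to
#'   `n_trees`), `oob_importance` (named), `n_trees`, `seed`.
#' @export
rf_root_importance <- function(table, n_trees = 1000L, seed = 1L) {
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  assert_two_classes(table)
  m <- feature_matrix(table)
  y <- factor(table$label, levels = c(0L, 1L))
  set.seed(seed)
  rf <- randomForest::randomForest(m, y, ntree = n_trees, importance = TRUE)
  root_var <- vapply(seq_len(n_trees), function(k) {
    tr <- randomForest::getTree(rf, k, labelVar = FALSE)
    as.integer(tr[1, "split var"])
  }, integer(1))
  counts <- tabulate(root_var, nbins = ncol(m))
  names(counts) <- colnames(m)
  oob <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  structure(list(root_counts = counts, oob_importance = oob,
                 n_trees = n_trees, seed = seed),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Random-forest importance (", x$n_trees, "trees )\n")
  ord <- order(x$root_counts, decreasing = TRUE)
  df <- data.frame(feature = names(x$root_counts)[ord],
                   root_count = x$root_counts[ord],
                   oob_importance = signif(x$oob_importance[ord], 3),
                   row.names = NULL)
  print(df)
  invisible(x)
}
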