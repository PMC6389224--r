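#' Canonical texture feature names
#'
#' The eleven GLCM quantifiers computed by [haralick_features()], in the
#' fixed column order used throughout the package.
#'
#' @return Character vector of length 11.
#' @export
texture_feature_names <- function() {
  c("energy", "entropy", "correlation", "contrast", "homogeneity",
    "variance", "sum_mean", "cluster_shade", "cluster_tendency",
    "max_probability", "inverse_variance")
}

#' Construct a feature table
#'
#' A feature table is the interface between feature extraction and the
#' statistics / classification stages: one row per subject, the eleven
#' canonical texture feature columns, a binary class label, and a subject
#' identifier. Class 1 is the positive class in all classifier metrics
#' (by convention the typically developing control group).
#'
#' @param features Numeric matrix or data frame, subjects x 11, with the
#'   canonical column names of [texture_feature_names()].
#' @param labels Integer vector of 0/1 class labels, one per subject.
#' @param subject_ids Character vector of unique subject identifiers;
#'   defaults to `"S001"`, `"S002"`, ...
#' @return A `feature_table`: a data frame with columns `subject_id`,
#'   `label`, then the 11 feature columns.
#' @export
feature_table <- function(features, labels,
                          subject_ids = sprintf("S%03d", seq_len(nrow(features)))) {
  features <- as.data.frame(features)
  canonical <- texture_feature_names()
  if (!identical(sort(names(features)), sort(canonical))) {
    stop("feature columns must be exactly the 11 canonical quantifier names; got: ",
         paste(names(features), collapse = ", "))
  }
  features <- features[, canonical]
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) {
    stop("labels length (", length(labels), ") does not match number of subjects (",
         nrow(features), ")")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 (class 1 = positive)")
  }
  if (anyNA(features)) stop("feature table contains missing values")
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  out <- data.frame(subject_id = as.character(subject_ids), label = labels,
                    features, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Extract the numeric feature matrix from a feature table
#' @param table A [feature_table()].
#' @return Numeric matrix, subjects x 11, row names = subject ids.
#' @export
feature_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table") || is.data.frame(table))
  m <- as.matrix(table[, texture_feature_names()])
  rownames(m) <- table$subject_id
  m
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x), "subjects (",
      sum(x$label == 0L), "class 0,", sum(x$label == 1L), "class 1 ),",
      length(texture_feature_names()), "texture features\n")
  NextMethod()
}

assert_two_classes <- function(table, min_per_class = 2L) {
  n0 <- sum(table$label == 0L); n1 <- sum(table$label == 1L)
  if (n0 < min_per_class || n1 < min_per_class) {
    stop("need at least ", min_per_class, " subjects per class; have ",
         n0, " and ", n1)
  }
  invisible(TRUE)
}
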