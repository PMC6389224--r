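#' Specify a synthetic two-class cohort
#'
#' Defines the generative conditions for a labeled phantom cohort: two
#' subject classes whose ellipsoidal regions of interest differ in spatial
#' texture (the correlation length of a Gaussian random field) while their
#' masked intensity histograms match in mean and spread by construction.
#' The default cohort mirrors a 14 + 14 age-matched design; the texture
#' parameters place the signal entirely in spatial autocorrelation, not in
#' first-order intensity statistics.
#'
#' @param n_class0,n_class1 Subjects per class (each >= 2). Class 1 is the
#'   positive class downstream.
#' @param volume_shape Voxel grid dimensions (default `c(40, 40, 40)`).
#' @param roi_semiaxes Ellipsoid semi-axes in voxels (default `c(12, 10, 9)`,
#'   about 3300 voxels — the scale of a hippocampus at low resolution).
#' @param texture_class0,texture_class1 Lists with `correlation_length`
#'   (Gaussian smoothing SD in voxels, > 0), `noise_sd` (intensity units,
#'   >= 0) and `mean_intensity`. Defaults: correlation lengths 1.5 vs 4
#'   (class 0 rougher), common noise_sd 10 and mean 100.
#' @param mask_error_rate Fraction of boundary voxels flipped to form the
#'   second-rater mask, in `[0, 0.5)`. The default 0.1 yields Dice overlap
#'   near 0.9, typical of expert inter-rater agreement on small structures.
#' @param age_range Cohort age span in years (default 4-15, a typical
#'   paediatric age-matched design). Cases and controls are matched in
#'   pairs sharing one age; with unequal class sizes the surplus subjects
#'   get unmatched ages.
#' @param age_slope Change of correlation length per year of age (default
#'   0.12): texture smoothens with development, making age the dominant
#'   shared latent within each matched pair.
#' @param cl_jitter SD of the per-subject correlation-length jitter around
#'   the class + age trend (default 0.08).
#' @param seed RNG seed; identical seed + spec give a bit-identical cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_class0 = 14L, n_class1 = 14L,
                        volume_shape = c(40L, 40L, 40L),
                        roi_semiaxes = c(12, 10, 9),
                        texture_class0 = list(correlation_length = 1.5,
                                              noise_sd = 10,
                                              mean_intensity = 100),
                        texture_class1 = list(correlation_length = 4,
                                              noise_sd = 10,
                                              mean_intensity = 100),
                        mask_error_rate = 0.1,
                        age_range = c(4, 15),
                        age_slope = 0.12,
                        cl_jitter = 0.08,
                        seed = 1L) {
  spec <- list(n_class0 = as.integer(n_class0), n_class1 = as.integer(n_class1),
               volume_shape = as.integer(volume_shape),
               roi_semiaxes = as.numeric(roi_semiaxes),
               texture_class0 = texture_class0, texture_class1 = texture_class1,
               mask_error_rate = mask_error_rate,
               age_range = as.numeric(age_range),
               age_slope = as.numeric(age_slope),
               cl_jitter = as.numeric(cl_jitter),
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_class0 < 2L) stop("invalid cohort spec: n_class0 must be >= 2")
  if (spec$n_class1 < 2L) stop("invalid cohort spec: n_class1 must be >= 2")
  if (length(spec$volume_shape) != 3L || any(spec$volume_shape < 4L)) {
    stop("invalid cohort spec: volume_shape must be 3 dimensions of at least 4 voxels")
  }
  if (length(spec$roi_semiaxes) != 3L || any(spec$roi_semiaxes <= 0)) {
    stop("invalid cohort spec: roi_semiaxes must be 3 positive values")
  }
  for (cl in c("texture_class0", "texture_class1")) {
    tp <- spec[[cl]]
    if (is.null(tp$correlation_length) || tp$correlation_length <= 0) {
      stop("invalid cohort spec: ", cl, "$correlation_length must be > 0")
    }
    if (is.null(tp$noise_sd) || tp$noise_sd < 0) {
      stop("invalid cohort spec: ", cl, "$noise_sd must be >= 0")
    }
    if (is.null(tp$mean_intensity)) {
      stop("invalid cohort spec: ", cl, "$mean_intensity is required")
    }
  }
  if (spec$mask_error_rate < 0 || spec$mask_error_rate >= 0.5) {
    stop("invalid cohort spec: mask_error_rate must be in [0, 0.5)")
  }
  if (length(spec$age_range) != 2L || diff(spec$age_range) < 0) {
    stop("invalid cohort spec: age_range must be an increasing pair")
  }
  if (spec$cl_jitter < 0) stop("invalid cohort spec: cl_jitter must be >= 0")
  invisible(spec)
}

# Centered ellipsoid mask on an integer grid.
ellipsoid_mask <- function(shape, semiaxes) {
  ctr <- (shape + 1) / 2
  x <- (seq_len(shape[1]) - ctr[1]) / semiaxes[1]
  y <- (seq_len(shape[2]) - ctr[2]) / semiaxes[2]
  z <- (seq_len(shape[3]) - ctr[3]) / semiaxes[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(d2 <= 1, dim = shape)
}

# Separable Gaussian smoothing of a 3D array, kernel SD `sigma` voxels.
# Edge-renormalized (each output is a weighted mean of available neighbors).
smooth_gaussian3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  dm <- dim(a)
  for (axis in 1:3) {
    a <- aperm(a, c(axis, setdiff(1:3, axis)))
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    K <- banded_kernel_matrix(da[1], k, half)
    m <- K %*% m
    a <- array(m, dim = da)
    a <- aperm(a, order(c(axis, setdiff(1:3, axis))))
  }
  a
}

banded_kernel_matrix <- function(n, k, half) {
  K <- matrix(0, n, n)
  for (off in -half:half) {
    w <- k[off + half + 1]
    idx <- seq_len(n)
    j <- idx + off
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + w
  }
  K / rowSums(K)
}

# One Gaussian-random-field volume: white noise smoothed at `corr_len`,
# standardized over the in-mask voxels so the masked histogram has mean
# `mean_int` and SD `noise_sd` exactly (texture, not intensity, carries
# any class difference).
grf_volume <- function(shape, mask, corr_len, noise_sd, mean_int) {
  if (noise_sd == 0) return(array(mean_int, dim = shape))
  w <- array(stats::rnorm(prod(shape)), dim = shape)
  f <- smooth_gaussian3d(w, corr_len)
  mv <- f[mask]
  f <- (f - mean(mv)) / stats::sd(mv)
  f * noise_sd + mean_int
}

#' Simulate a labeled synthetic cohort
#'
#' Generates one subject per row of the design: a 3D Gaussian-random-field
#' volume whose correlation length combines the class base value, a shared
#' developmental (age) trend and per-subject jitter, plus an ellipsoidal
#' first-rater mask and a boundary-perturbed second-rater mask. Cases and
#' controls are matched in pairs sharing one age, mirroring an age-matched
#' case-control design; with unequal class sizes the surplus subjects carry
#' unmatched ages. Masked intensities are standardized within the mask, so
#' the two classes' masked histograms share mean and SD exactly and differ
#' only in spatial structure.
#'
#' @param spec A [cohort_spec()].
#' @return List of subjects; each has `volume`, `mask_rater1`, `mask_rater2`,
#'   `label` (0/1), `age` and `subject_id`.
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  mask <- ellipsoid_mask(spec$volume_shape, spec$roi_semiaxes)
  n0 <- spec$n_class0; n1 <- spec$n_class1
  n_pairs <- min(n0, n1)
  pair_ages <- stats::runif(n_pairs, spec$age_range[1], spec$age_range[2])
  extra_ages <- stats::runif(n0 + n1 - 2L * n_pairs,
                             spec$age_range[1], spec$age_range[2])
  labels <- c(rep(0L, n0), rep(1L, n1))
  ages <- c(pair_ages, extra_ages[seq_len(n0 - n_pairs)],
            pair_ages, extra_ages[seq_len(n1 - n_pairs) + (n0 - n_pairs)])
  mid_age <- mean(spec$age_range)
  lapply(seq_along(labels), function(i) {
    tp <- if (labels[i] == 0L) spec$texture_class0 else spec$texture_class1
    cl <- tp$correlation_length + spec$age_slope * (ages[i] - mid_age) +
      stats::rnorm(1, 0, spec$cl_jitter)
    cl <- max(cl, 0.3)
    vol <- grf_volume(spec$volume_shape, mask, cl, tp$noise_sd,
                      tp$mean_intensity)
    m2_seed <- sample.int(.Machine$integer.max, 1L)
    m2 <- if (spec$mask_error_rate > 0) {
      perturb_mask(mask, spec$mask_error_rate, seed = m2_seed)
    } else mask
    list(volume = vol, mask_rater1 = mask, mask_rater2 = m2,
         label = labels[i], age = ages[i], subject_id = sprintf("S%03d", i))
  })
}

#' Perturb a binary mask at its boundary
#'
#' Emulates a second rater's segmentation by flipping a fraction of the
#' boundary voxels — in-mask voxels with an out-of-mask 6-neighbor and
#' out-of-mask voxels with an in-mask 6-neighbor. Disagreement between
#' expert raters concentrates at structure borders, which this mimics.
#'
#' @param mask Binary 3D array, nonempty.
#' @param error_rate Flip probability per boundary voxel, in `[0, 0.5)`.
#' @param seed RNG seed for reproducibility.
#' @return Perturbed logical array of the same shape, guaranteed nonempty.
#' @export
perturb_mask <- function(mask, error_rate, seed = NULL) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("cannot perturb an empty mask")
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must be in [0, 0.5)")
  }
  if (error_rate == 0) return(mask)
  if (!is.null(seed)) set.seed(seed)
  nb <- neighbor_count(mask)
  boundary <- (mask & nb < 6L) | (!mask & nb > 0L)
  idx <- which(boundary)
  flip <- idx[stats::runif(length(idx)) < error_rate]
  out <- mask
  out[flip] <- !out[flip]
  if (!any(out)) stop("perturbation emptied the mask; lower error_rate")
  out
}

# Number of in-mask 6-neighbors per voxel (out-of-bounds counts as out-of-mask).
neighbor_count <- function(mask) {
  dm <- dim(mask)
  nb <- array(0L, dim = dm)
  m <- mask * 1L
  shift <- function(a, axis, by) {
    out <- array(0L, dim = dm)
    n <- dm[axis]
    if (by == 1L) {
      src <- 1:(n - 1); dst <- 2:n
    } else {
      src <- 2:n; dst <- 1:(n - 1)
    }
    ix <- function(which_axis, range) {
      lst <- lapply(dm, seq_len)
      lst[[which_axis]] <- range
      lst
    }
    do.call(`[<-`, c(list(out), ix(axis, dst), list(value = do.call(`[`, c(list(a), ix(axis, src))))))
  }
  for (axis in 1:3) {
    nb <- nb + shift(m, axis, 1L) + shift(m, axis, -1L)
  }
  nb
}

#' Simulate a feature table directly
#'
#' Draws each of the 11 texture features independently from a normal
#' location-scale model, per class, bypassing image synthesis. Useful for
#' calibrating the statistics and classification stages in isolation.
#'
#' @param n_class0,n_class1 Subjects per class (>= 1 each; >= 2 for any
#'   downstream statistics).
#' @param means_class0,means_class1 Numeric vectors of 11 per-feature means.
#' @param sds Numeric vector of 11 per-feature SDs (> 0), shared by both
#'   classes.
#' @param seed RNG seed.
#' @return A [feature_table()].
#' @export
simulate_feature_table <- function(n_class0, n_class1,
                                   means_class0 = rep(0, 11),
                                   means_class1 = rep(0, 11),
                                   sds = rep(1, 11), seed = 1L) {
  n_class0 <- as.integer(n_class0); n_class1 <- as.integer(n_class1)
  if (n_class0 < 1L || n_class1 < 1L) {
    stop("n_class0 and n_class1 must be >= 1")
  }
  nf <- length(texture_feature_names())
  if (length(means_class0) != nf || length(means_class1) != nf ||
      length(sds) != nf) {
    stop("means_class0, means_class1 and sds must each have length ", nf)
  }
  if (any(sds <= 0)) stop("all sds must be > 0")
  set.seed(seed)
  n <- n_class0 + n_class1
  labels <- c(rep(0L, n_class0), rep(1L, n_class1))
  means <- rbind(matrix(means_class0, n_class0, nf, byrow = TRUE),
                 matrix(means_class1, n_class1, nf, byrow = TRUE))
  x <- means + matrix(stats::rnorm(n * nf), n, nf) %*% diag(sds)
  colnames(x) <- texture_feature_names()
  feature_table(x, labels)
}

#' Simulate an age-matched case-control feature table
#'
#' Emulates the feature covariance of an age-matched paired design: each of
#' `n_pairs` pairs (one case, one control) shares pair-level latent factors
#' (developmental stage and a second morphometric factor) that load on all
#' 11 texture features with mixed signs — smoothness-type quantifiers
#' (correlation, homogeneity, energy, maximum probability, variance,
#' sum-mean, cluster tendency) move together and opposite to the
#' heterogeneity-type ones (entropy, contrast, inverse variance, cluster
#' shade) — plus small idiosyncratic noise. Because the latent variation
#' shared within pairs dominates the noise, matched partners are close in
#' feature space, the geometry the classifier sees in a matched cohort.
#' With `class_shift = 0` the table is uninformative about the class label.
#'
#' @param n_pairs Number of matched case-control pairs (default 14).
#' @param class_shift Numeric vector of 11 per-feature shifts added to the
#'   class-1 member of every pair (default all 0: no class signal).
#' @param noise_sd SD of the idiosyncratic per-subject noise relative to
#'   the unit-scale latent factors (default 0.04).
#' @param seed RNG seed.
#' @return A [feature_table()] with `2 * n_pairs` rows; labels alternate
#'   0, 1 within consecutive pairs.
#' @export
simulate_matched_table <- function(n_pairs = 14L, class_shift = rep(0, 11),
                                   noise_sd = 0.04, seed = 1L) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 2L) stop("n_pairs must be >= 2")
  nf <- length(texture_feature_names())
  if (length(class_shift) != nf) stop("class_shift must have length ", nf)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  # +1 for smoothness-type quantifiers, -1 for heterogeneity-type ones
  sgn <- c(energy = 1, entropy = -1, correlation = 1, contrast = -1,
           homogeneity = 1, variance = 1, sum_mean = 1, cluster_shade = -1,
           cluster_tendency = -1, max_probability = 1, inverse_variance = -1)
  load1 <- sgn * stats::rnorm(nf, 1, 0.25)
  load2 <- stats::rnorm(nf, 0, 0.4)
  u <- stats::rnorm(n_pairs)   # developmental latent, one per pair
  v <- stats::rnorm(n_pairs)   # secondary morphometric latent
  n <- 2L * n_pairs
  pair_of <- rep(seq_len(n_pairs), each = 2L)
  labels <- rep(c(0L, 1L), n_pairs)
  x <- outer(u[pair_of], load1) + outer(v[pair_of], load2) +
    matrix(stats::rnorm(n * nf, 0, noise_sd), n, nf) +
    outer(labels, class_shift)
  colnames(x) <- texture_feature_names()
  feature_table(x, labels)
}
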