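#' Quantize a masked region to discrete grey levels
#'
#' Rank-based (histogram-equalized) assignment of the in-mask intensities to
#' `Ng` equal-count bins, the standard pre-processing step before GLCM
#' counting. Only in-mask voxels participate; the mapping is monotone in
#' intensity, so any texture feature computed downstream is invariant under
#' strictly monotone intensity transforms of the input. Ties are broken by
#' voxel (storage) order, so voxels sharing an intensity may straddle a bin
#' boundary; a region of constant intensity maps entirely to level 0.
#'
#' @param volume 3D (or 2D) numeric array of intensities.
#' @param mask Logical/0-1 array of the same shape; TRUE marks the region.
#' @param Ng Number of grey levels (default 32).
#' @param bin_mode `"equalize"` (rank-based equal-count bins, default) or
#'   `"uniform"` (equal-width bins over the in-mask intensity range).
#' @return A `quantized_region`: list with `levels` (integer array, in-mask
#'   voxels in `[0, Ng-1]`, NA outside), `mask` (logical array) and `Ng`.
#' @export
quantize_region <- function(volume, mask, Ng = 32L,
                            bin_mode = c("equalize", "uniform")) {
  bin_mode <- match.arg(bin_mode)
  Ng <- as.integer(Ng)
  if (Ng < 2L) stop("Ng must be at least 2")
  if (!identical(dim(volume), dim(mask) %||% dim(volume)) ||
      length(volume) != length(mask)) {
    stop("volume and mask shapes differ")
  }
  mask <- array(as.logical(mask), dim = dim(volume))
  n <- sum(mask)
  if (n == 0L) stop("mask is empty: no in-mask voxels to quantize")
  vals <- volume[mask]
  levels <- array(NA_integer_, dim = dim(volume))
  if (length(unique(vals)) == 1L) {
    levels[mask] <- 0L
  } else if (bin_mode == "equalize") {
    # equal-count bins; ties.method = "first" breaks intensity ties by voxel order
    r <- rank(vals, ties.method = "first")
    levels[mask] <- as.integer(ceiling(r * Ng / n) - 1L)
  } else {
    rng <- range(vals)
    lv <- floor((vals - rng[1]) / (rng[2] - rng[1]) * Ng)
    levels[mask] <- as.integer(pmin(lv, Ng - 1L))
  }
  structure(list(levels = levels, mask = mask, Ng = Ng),
            class = "quantized_region")
}

# Displacement (dr, dc) for a slice stored as a matrix (rows = first in-slice
# axis, columns = second). Angles follow the usual image convention: 0 deg is
# along the column axis, 90 deg along the row axis, with 45/135 the diagonals.
glcm_offset <- function(d, theta) {
  th <- as.numeric(theta) %% 360
  off <- switch(as.character(th),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    "180" = c(0L, -d),
    "225" = c(d, -d),
    "270" = c(d, 0L),
    "315" = c(d, d),
    stop("direction theta must be a multiple of 45 degrees; got ", theta)
  )
  as.integer(off)
}

#' Grey-level co-occurrence matrix of a 2D quantized slice
#'
#' Counts ordered pixel pairs `(p, p + (dr,dc))` whose members are both
#' in-mask, accumulating `counts[i+1, j+1]` when the first pixel has level
#' `i` and the second level `j`. Counts are not symmetrized: the matrix for
#' the reversed displacement (theta + 180 deg) is the transpose.
#'
#' @param slice_levels Integer matrix of grey levels in `[0, Ng-1]` (NA
#'   allowed outside the mask).
#' @param slice_mask Logical matrix, same shape.
#' @param d Offset distance in pixels (>= 1).
#' @param theta Direction in degrees; one of 0, 45, 90, 135 (or their
#'   redundant opposites).
#' @param Ng Number of grey levels.
#' @param symmetrize If TRUE, fold in the transposed counts (the reversed
#'   displacement) so the matrix is symmetric.
#' @return A `glcm`: list with `counts` (Ng x Ng integer matrix), `d`,
#'   `theta`, `Ng` and `n_pairs`. A slice with no valid pair returns
#'   `n_pairs = 0` and zero counts; downstream aggregation skips it.
#' @export
compute_glcm <- function(slice_levels, slice_mask, d = 1L, theta = 0,
                         Ng, symmetrize = FALSE) {
  d <- as.integer(d)
  if (d < 1L) stop("offset d must be >= 1")
  if (missing(Ng)) stop("Ng (number of grey levels) must be supplied")
  Ng <- as.integer(Ng)
  slice_levels <- as.matrix(slice_levels)
  slice_mask <- matrix(as.logical(slice_mask), nrow = nrow(slice_levels))
  off <- glcm_offset(d, theta)
  nr <- nrow(slice_levels); nc <- ncol(slice_levels)

  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  counts <- matrix(0L, Ng, Ng)
  n_pairs <- 0L
  if (length(r1) > 0L && length(c1) > 0L &&
      min(r1) >= 1L && max(r1) <= nr && min(c1) >= 1L && max(c1) <= nc) {
    a <- slice_levels[r1, c1, drop = FALSE]
    b <- slice_levels[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- slice_mask[r1, c1, drop = FALSE] &
      slice_mask[r1 + off[1], c1 + off[2], drop = FALSE]
    i <- a[ok]; j <- b[ok]
    n_pairs <- length(i)
    if (n_pairs > 0L) {
      tab <- tabulate(i * Ng + j + 1L, nbins = Ng * Ng)
      counts <- matrix(as.integer(tab), Ng, Ng, byrow = TRUE)
    }
  }
  if (symmetrize) {
    counts <- counts + t(counts)
    n_pairs <- 2L * n_pairs
  }
  structure(list(counts = counts, d = d, theta = theta, Ng = Ng,
                 n_pairs = n_pairs),
            class = "glcm")
}

#' Normalize a GLCM to a probability matrix
#'
#' @param g A `glcm` from [compute_glcm()].
#' @return Ng x Ng numeric matrix summing to 1.
#' @export
normalize_glcm <- function(g) {
  stopifnot(inherits(g, "glcm"))
  if (g$n_pairs == 0L) stop("cannot normalize a GLCM with no valid pixel pairs")
  g$counts / g$n_pairs
}

#' Haralick-type texture quantifiers of a normalized GLCM
#'
#' Computes the eleven scalar texture descriptors from a co-occurrence
#' probability matrix `p` with entries `p(i, j)`, grey levels indexed
#' `0..Ng-1`. With marginals `px`, `py`, marginal means `mux`, `muy` and
#' SDs `sx`, `sy`:
#' \itemize{
#'   \item energy = sum p^2
#'   \item entropy = -sum p log2 p (0 log 0 := 0)
#'   \item correlation = sum (i - mux)(j - muy) p / (sx sy), 0 if sx sy = 0
#'   \item contrast = sum (i - j)^2 p
#'   \item homogeneity = sum p / (1 + |i - j|)
#'   \item variance = sum (i - mu)^2 p, mu = sum (i + j)/2 p (the grand mean)
#'   \item sum_mean = 1/2 sum (i + j) p
#'   \item cluster_shade = sum (i + j - mux - muy)^3 p
#'   \item cluster_tendency = sum (i + j - mux - muy)^2 p
#'   \item max_probability = max p
#'   \item inverse_variance = sum over i != j of p / (i - j)^2
#' }
#'
#' @param p Ng x Ng numeric matrix of co-occurrence probabilities (sums
#'   to 1), as returned by [normalize_glcm()].
#' @return Named numeric vector of length 11 ([texture_feature_names()]).
#' @export
haralick_features <- function(p) {
  p <- as.matrix(p)
  Ng <- nrow(p)
  if (ncol(p) != Ng) stop("p must be square")
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1 (normalize the GLCM first)")

  iv <- seq_len(Ng) - 1
  I <- matrix(iv, Ng, Ng)        # row level i
  J <- matrix(iv, Ng, Ng, byrow = TRUE)  # column level j

  px <- rowSums(p); py <- colSums(p)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sx <- sqrt(sum((iv - mux)^2 * px)); sy <- sqrt(sum((iv - muy)^2 * py))

  energy <- sum(p^2)
  pp <- p[p > 0]
  entropy <- -sum(pp * log2(pp))
  correlation <- if (sx * sy > 0) sum((I - mux) * (J - muy) * p) / (sx * sy) else 0
  contrast <- sum((I - J)^2 * p)
  homogeneity <- sum(p / (1 + abs(I - J)))
  sum_mean <- 0.5 * sum((I + J) * p)
  variance <- sum((I - sum_mean)^2 * p)
  cs <- I + J - mux - muy
  cluster_shade <- sum(cs^3 * p)
  cluster_tendency <- sum(cs^2 * p)
  max_probability <- max(p)
  offd <- I != J
  inverse_variance <- sum(p[offd] / (I[offd] - J[offd])^2)

  c(energy = energy, entropy = entropy, correlation = correlation,
    contrast = contrast, homogeneity = homogeneity, variance = variance,
    sum_mean = sum_mean, cluster_shade = cluster_shade,
    cluster_tendency = cluster_tendency, max_probability = max_probability,
    inverse_variance = inverse_variance)
}

#' Texture feature vector of one masked region
#'
#' The full per-region extraction: quantize the 3D region once, slice it
#' along the chosen plane, compute one GLCM per (slice, direction) at offset
#' `d`, apply the eleven quantifiers to each normalized GLCM, and average
#' each feature over all valid (slice, direction) pairs. GLCMs with no valid
#' in-mask pair are skipped rather than imputed.
#'
#' @param volume 3D numeric intensity array.
#' @param mask Binary 3D array marking the region.
#' @param plane Slicing axis: 1 = sagittal (default), 2 = coronal,
#'   3 = axial, or the equivalent names.
#' @param d Pixel offset (default 1).
#' @param thetas Directions in degrees (default `c(0, 45, 90, 135)`).
#' @param Ng Grey levels for quantization (default 32).
#' @param symmetrize Fold in transposed counts per GLCM (default FALSE).
#' @param bin_mode Quantization mode, see [quantize_region()].
#' @return Named numeric vector of the 11 averaged features, with
#'   attribute `n_glcms` = number of (slice, direction) GLCMs averaged.
#' @export
region_features <- function(volume, mask, plane = 1L, d = 1L,
                            thetas = c(0, 45, 90, 135), Ng = 32L,
                            symmetrize = FALSE,
                            bin_mode = c("equalize", "uniform")) {
  bin_mode <- match.arg(bin_mode)
  plane <- match_plane(plane)
  q <- quantize_region(volume, mask, Ng = Ng, bin_mode = bin_mode)

  # slices along `plane` that contain any mask voxel
  idx_axes <- setdiff(1:3, plane)
  present <- apply(q$mask, plane, any)
  feats <- NULL
  n_glcms <- 0L
  for (s in which(present)) {
    sl <- slice_array(q$levels, plane, s)
    sm <- slice_array(q$mask, plane, s)
    for (th in thetas) {
      g <- compute_glcm(sl, sm, d = d, theta = th, Ng = q$Ng,
                        symmetrize = symmetrize)
      if (g$n_pairs == 0L) next
      f <- haralick_features(normalize_glcm(g))
      feats <- if (is.null(feats)) f else feats + f
      n_glcms <- n_glcms + 1L
    }
  }
  if (n_glcms == 0L) {
    stop("region yields no valid GLCM in any slice (mask too thin for offset d=", d, ")")
  }
  out <- feats / n_glcms
  attr(out, "n_glcms") <- n_glcms
  out
}

match_plane <- function(plane) {
  if (is.character(plane)) {
    plane <- match.arg(plane, c("sagittal", "coronal", "axial"))
    plane <- match(plane, c("sagittal", "coronal", "axial"))
  }
  plane <- as.integer(plane)
  if (!plane %in% 1:3) stop("plane must be 1..3 or sagittal/coronal/axial")
  plane
}

slice_array <- function(a, axis, i) {
  switch(axis, a[i, , ], a[, i, ], a[, , i])
}

#' Extract features for every subject of a cohort
#'
#' Applies [region_features()] to each subject's volume and first-rater
#' mask and assembles the results into a [feature_table()].
#'
#' @param cohort List of subjects as produced by [simulate_cohort()] or
#'   [ingest_cohort()]: each element has `volume`, `mask_rater1`, `label`,
#'   `subject_id`.
#' @inheritParams region_features
#' @return A [feature_table()].
#' @export
extract_cohort_features <- function(cohort, plane = 1L, d = 1L,
                                    thetas = c(0, 45, 90, 135), Ng = 32L,
                                    symmetrize = FALSE,
                                    bin_mode = c("equalize", "uniform")) {
  bin_mode <- match.arg(bin_mode)
  rows <- lapply(cohort, function(s) {
    region_features(s$volume, s$mask_rater1, plane = plane, d = d,
                    thetas = thetas, Ng = Ng, symmetrize = symmetrize,
                    bin_mode = bin_mode)
  })
  feature_table(do.call(rbind, rows),
                labels = vapply(cohort, `[[`, integer(1), "label"),
                subject_ids = vapply(cohort, `[[`, character(1), "subject_id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
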