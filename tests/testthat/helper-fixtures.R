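# Shared fixtures: small grids and cohorts built in code at test time.

# brute-force GLCM oracle: exhaustive enumeration of ordered in-mask pairs
glcm_bruteforce <- function(levels, mask, d, theta, Ng) {
  off <- roitexture:::glcm_offset(d, theta)
  counts <- matrix(0L, Ng, Ng)
  for (r in seq_len(nrow(levels))) {
    for (cc in seq_len(ncol(levels))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
      if (!mask[r, cc] || !mask[r2, c2]) next
      i <- levels[r, cc]; j <- levels[r2, c2]
      counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1L
    }
  }
  counts
}

# brute-force double-loop Haralick oracle, independent of the implementation
haralick_bruteforce <- function(p) {
  Ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + (i - 1) * px[i]; muy <- muy + (i - 1) * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:Ng) { sx2 <- sx2 + (i - 1 - mux)^2 * px[i]; sy2 <- sy2 + (i - 1 - muy)^2 * py[i] }
  energy <- 0; entropy <- 0; corr <- 0; contrast <- 0; homog <- 0
  summean <- 0; shade <- 0; tend <- 0; invvar <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    v <- p[i, j]; a <- i - 1; b <- j - 1
    energy <- energy + v^2
    if (v > 0) entropy <- entropy - v * log2(v)
    corr <- corr + (a - mux) * (b - muy) * v
    contrast <- contrast + (a - b)^2 * v
    homog <- homog + v / (1 + abs(a - b))
    summean <- summean + 0.5 * (a + b) * v
    shade <- shade + (a + b - mux - muy)^3 * v
    tend <- tend + (a + b - mux - muy)^2 * v
    if (a != b) invvar <- invvar + v / (a - b)^2
  }
  variance <- 0
  for (i in 1:Ng) for (j in 1:Ng) variance <- variance + (i - 1 - summean)^2 * p[i, j]
  c(energy = energy, entropy = entropy,
    correlation = if (sx2 * sy2 > 0) corr / sqrt(sx2 * sy2) else 0,
    contrast = contrast, homogeneity = homog, variance = variance,
    sum_mean = summean, cluster_shade = shade, cluster_tendency = tend,
    max_probability = max(p), inverse_variance = invvar)
}

random_prob_matrix <- function(Ng) {
  m <- matrix(stats::rexp(Ng * Ng), Ng, Ng)
  m / sum(m)
}

random_masked_grid <- function(nr, nc, Ng, p_mask = 0.7) {
  levels <- matrix(sample(0:(Ng - 1), nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(stats::runif(nr * nc) < p_mask, nr, nc)
  list(levels = levels, mask = mask)
}

# small fast cohort spec for pipeline-level tests
tiny_cohort_spec <- function(n0 = 4L, n1 = 4L, seed = 1L, ...) {
  cohort_spec(n_class0 = n0, n_class1 = n1,
              volume_shape = c(20L, 20L, 20L), roi_semiaxes = c(6, 5, 4),
              seed = seed, ...)
}

# brute-force Holm step-down, written straight from the definition
holm_bruteforce <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) reject[ord[k]] <- TRUE else break
  }
  reject
}
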