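test_that("quantization is rank-based, monotone, and handles degenerate input", {
  vol <- array(0, c(4, 4, 2)); mask <- array(TRUE, c(4, 4, 2))

  # constant region maps entirely to level 0
  q <- quantize_region(vol, mask, Ng = 32)
  expect_true(all(q$levels[mask] == 0L))

  # 32 distinct intensities into 32 levels: each level used exactly once
  set.seed(1)
  vol2 <- array(sample(1:32), c(4, 4, 2))
  q2 <- quantize_region(vol2, mask, Ng = 32)
  expect_equal(as.integer(table(q2$levels[mask])), rep(1L, 32))
  # monotone in intensity
  ord <- order(vol2[mask])
  expect_true(all(diff(q2$levels[mask][ord]) >= 0))

  # default Ng in the full extraction path is 32
  expect_equal(formals(region_features)$Ng, 32L)

  expect_error(quantize_region(vol, array(FALSE, dim(vol))), "empty")
  expect_error(quantize_region(vol, mask, Ng = 1), "Ng")
})

test_that("GLCM counts match hand-enumerated examples", {
  # 4x4 constant image, d=1, theta=0: 4 rows x 3 horizontal pairs
  lv <- matrix(2L, 4, 4); mk <- matrix(TRUE, 4, 4)
  g <- compute_glcm(lv, mk, d = 1, theta = 0, Ng = 4)
  expect_equal(g$n_pairs, 12L)
  expect_equal(g$counts[3, 3], 12L)
  expect_equal(sum(g$counts), 12L)

  # 2x2 image [[0,1],[0,1]] (rows), d=1, theta=0: two ordered (0,1) pairs
  lv2 <- rbind(c(0L, 1L), c(0L, 1L))
  g2 <- compute_glcm(lv2, matrix(TRUE, 2, 2), d = 1, theta = 0, Ng = 2)
  expect_equal(g2$counts, matrix(c(0L, 0L, 2L, 0L), 2, 2))
  expect_equal(g2$n_pairs, 2L)

  # no valid pair: offset larger than grid
  g3 <- compute_glcm(lv2, matrix(TRUE, 2, 2), d = 5, theta = 0, Ng = 2)
  expect_equal(g3$n_pairs, 0L)
  expect_error(normalize_glcm(g3), "no valid")
})

test_that("GLCM counts equal exhaustive pair enumeration on random masked grids", {
  set.seed(42)
  for (rep in 1:6) {
    gr <- random_masked_grid(sample(5:16, 1), sample(5:16, 1), Ng = 6)
    for (d in 1:4) {
      for (th in c(0, 45, 90, 135)) {
        g <- compute_glcm(gr$levels, gr$mask, d = d, theta = th, Ng = 6)
        bf <- glcm_bruteforce(gr$levels, gr$mask, d, th, 6)
        expect_identical(g$counts, bf)
        expect_identical(g$n_pairs, sum(bf))
      }
    }
  }
})

test_that("reversed displacement gives the transposed GLCM", {
  set.seed(7)
  for (rep in 1:100) {
    gr <- random_masked_grid(8, 8, Ng = 4)
    th <- sample(c(0, 45, 90, 135), 1)
    d <- sample(1:2, 1)
    g <- compute_glcm(gr$levels, gr$mask, d = d, theta = th, Ng = 4)
    grev <- compute_glcm(gr$levels, gr$mask, d = d, theta = th + 180, Ng = 4)
    expect_identical(g$counts, t(grev$counts))
  }
})

test_that("normalized GLCM is a probability matrix", {
  set.seed(3)
  gr <- random_masked_grid(10, 10, Ng = 5)
  g <- compute_glcm(gr$levels, gr$mask, d = 1, theta = 45, Ng = 5)
  p <- normalize_glcm(g)
  expect_equal(sum(p), 1, tolerance = 1e-14)
  expect_true(all(p >= 0))
})

test_that("quantifiers match the brute-force double-loop oracle to 1e-12", {
  set.seed(99)
  for (rep in 1:50) {
    p <- random_prob_matrix(8)
    expect_equal(haralick_features(p), haralick_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("quantifier constant-texture and uniform limits are exact", {
  # all mass on one diagonal cell
  p <- matrix(0, 5, 5); p[3, 3] <- 1
  f <- haralick_features(p)
  expect_identical(unname(f[c("energy", "entropy", "contrast", "homogeneity",
                              "max_probability", "inverse_variance",
                              "correlation")]),
                   c(1, 0, 0, 1, 1, 0, 0))

  # uniform 2x2: hand computation over the 4 cells
  p2 <- matrix(0.25, 2, 2)
  f2 <- haralick_features(p2)
  expect_equal(unname(f2["energy"]), 0.25)
  expect_equal(unname(f2["entropy"]), 2)
  expect_equal(unname(f2["contrast"]), 0.5)
  expect_equal(unname(f2["max_probability"]), 0.25)

  expect_length(f2, 11)
  expect_named(f2, texture_feature_names())
})

test_that("region features are invariant under strictly monotone intensity transforms", {
  set.seed(5)
  vol <- array(rnorm(20^3, 50, 5), c(20, 20, 20))
  mask <- roitexture:::ellipsoid_mask(c(20L, 20L, 20L), c(6, 5, 4))
  f0 <- region_features(vol, mask)
  expect_equal(region_features(2 * vol + 7, mask), f0, tolerance = 1e-12)
  expect_equal(region_features(vol^3, mask), f0, tolerance = 1e-12)  # positive data
})

test_that("adding the redundant reversed directions equals symmetrized counts", {
  set.seed(8)
  gr <- random_masked_grid(12, 12, Ng = 5)
  for (th in c(0, 45, 90, 135)) {
    gs <- compute_glcm(gr$levels, gr$mask, d = 1, theta = th, Ng = 5,
                       symmetrize = TRUE)
    gf <- compute_glcm(gr$levels, gr$mask, d = 1, theta = th, Ng = 5)
    gb <- compute_glcm(gr$levels, gr$mask, d = 1, theta = th + 180, Ng = 5)
    expect_identical(gs$counts, gf$counts + gb$counts)
    expect_identical(gs$n_pairs, gf$n_pairs + gb$n_pairs)
  }
})

test_that("per-region aggregation averages per-slice per-direction quantifiers", {
  # region confined to a single slice: result is the plain mean of the
  # 4 direction-features of that slice
  set.seed(11)
  vol <- array(rnorm(16 * 16 * 5), c(5, 16, 16))
  mask <- array(FALSE, c(5, 16, 16)); mask[3, 4:13, 4:13] <- TRUE
  f <- region_features(vol, mask, plane = 1, Ng = 8)
  q <- quantize_region(vol, mask, Ng = 8)
  per_dir <- sapply(c(0, 45, 90, 135), function(th) {
    g <- compute_glcm(q$levels[3, , ], q$mask[3, , ], d = 1, theta = th, Ng = 8)
    haralick_features(normalize_glcm(g))
  })
  expect_equal(unclass(f), rowMeans(per_dir), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(f, "n_glcms"), 4L)

  # zero-noise region: constant-texture limit survives averaging
  cvol <- array(5, c(8, 8, 8)); cmask <- array(TRUE, c(8, 8, 8))
  fc <- region_features(cvol, cmask, Ng = 32)
  expect_equal(unname(fc["entropy"]), 0)
  expect_equal(unname(fc["contrast"]), 0)

  # a mask too thin for any pair errors out
  thin <- array(FALSE, c(5, 16, 16)); thin[3, 5, 5] <- TRUE
  expect_error(region_features(vol, thin), "no valid GLCM")
})
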