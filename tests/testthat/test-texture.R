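# Texture-feature families against analytic fixtures and brute-force
# oracles, plus the full extractor's contracts.

const_roi <- function(dims = c(3, 3, 2), level = 1L, Ng = 4L) {
  lv <- array(level, dims)
  structure(list(levels = lv, n_levels = Ng, bin_edges = seq(0.5, Ng + 0.5),
                 degenerate = TRUE, n_voxels = prod(dims)),
            class = "discretized_roi")
}

test_that("constant-level ROI gives the single-cell GLCM closed form", {
  g <- glcm_features(const_roi())
  expect_equal(g$contrast, 0)
  expect_equal(g$dissimilarity, 0)
  expect_equal(g$homogeneity, 1)
  expect_equal(g$energy, 1)
  expect_equal(g$entropy, 0)
  expect_false(g$correlation_valid)
  expect_true(is.na(g$correlation))
})

test_that("checkerboard GLCM matches the two-cell closed form", {
  cb <- array(0L, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) cb[i, j, 1] <- 1L + (i + j) %% 2L
  roi <- structure(list(levels = cb, n_levels = 2L, degenerate = FALSE,
                        n_voxels = 16L), class = "discretized_roi")
  g <- glcm_features(roi, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(g$contrast, 1)
  expect_equal(g$dissimilarity, 1)
  expect_equal(g$homogeneity, 0.5)
  expect_equal(g$energy, 0.5)
})

test_that("single-run and all-singleton GLRLM closed forms hold", {
  rr <- structure(list(levels = array(1L, c(1, 4, 1)), n_levels = 1L,
                       degenerate = FALSE, n_voxels = 4L),
                  class = "discretized_roi")
  f <- glrlm_features(rr, directions = matrix(c(0L, 1L, 0L), 1))
  expect_equal(f$SRE, 1 / 16)
  expect_equal(f$LRE, 16)
  expect_equal(f$RP, 1 / 4)
  expect_equal(f$GLNU_r, 1)
  expect_equal(f$RLNU, 1)

  alt <- structure(list(levels = array(c(1L, 2L, 1L, 2L), c(1, 4, 1)),
                       n_levels = 2L, degenerate = FALSE, n_voxels = 4L),
                  class = "discretized_roi")
  f2 <- glrlm_features(alt, directions = matrix(c(0L, 1L, 0L), 1))
  expect_equal(f2$SRE, 1)
  expect_equal(f2$LRE, 1)
  expect_equal(f2$RP, 1)
})

test_that("single-zone and all-singleton GLZLM closed forms hold", {
  zz <- structure(list(levels = array(1L, c(2, 2, 1)), n_levels = 1L,
                       degenerate = FALSE, n_voxels = 4L),
                  class = "discretized_roi")
  z <- glzlm_features(zz)
  expect_equal(z$SZE, 1 / 16)
  expect_equal(z$LZE, 16)
  expect_equal(z$ZP, 1 / 4)

  uq <- structure(list(levels = array(1:8, c(2, 2, 2)), n_levels = 8L,
                       degenerate = FALSE, n_voxels = 8L),
                  class = "discretized_roi")
  z2 <- glzlm_features(uq)
  expect_equal(z2$ZP, 1)
  expect_equal(z2$SZE, 1)
})

test_that("NGLDM matches the hand-worked 3x3 instance and saturates", {
  cst <- ngldm_features(const_roi())
  expect_equal(cst$contrast, 0)
  expect_true(cst$saturated)
  expect_equal(cst$coarseness, 1e6)

  # 3x3x1, centre level 2 amid level 1: every voxel has in-mask neighbours.
  # Corner voxels (level 1): 3 neighbours {1,1,2}    -> |1 - 4/3| = 1/3 (x4)
  # Edge voxels  (level 1): 5 neighbours {1,1,1,2,1} -> |1 - 6/5| = 1/5 (x4)
  # Centre voxel (level 2): 8 neighbours, all 1      -> |2 - 1|  = 1    (x1)
  ar <- array(1L, c(3, 3, 1)); ar[2, 2, 1] <- 2L
  roi <- structure(list(levels = ar, n_levels = 2L, degenerate = FALSE,
                        n_voxels = 9L), class = "discretized_roi")
  f <- ngldm_features(roi)
  s1 <- 4 * (1 / 3) + 4 * (1 / 5)
  s2 <- 1
  p <- c(8, 1) / 9
  expect_equal(f$coarseness, 1 / (1e-6 + p[1] * s1 + p[2] * s2))
  expect_equal(f$contrast,
               (2 * p[1] * p[2] * 1) / (2 * 1) * (s1 + s2) / 9)
})

test_that("matrix features equal their brute-force oracles on random ROIs", {
  dirs <- directions_13()
  for (seed in 1:8) {
    roi <- make_random_roi(c(5, 5, 3), 4, seed)
    expect_equal(unlist(glcm_features(roi)[1:6]),
                 unlist(oracle_glcm_features(roi)), tolerance = 1e-12)
    expect_equal(unlist(glrlm_features(roi)),
                 unlist(oracle_glrlm_features(roi)), tolerance = 1e-12)
    expect_equal(unlist(glzlm_features(roi)),
                 unlist(oracle_glzlm_features(roi)), tolerance = 1e-12)
    expect_equal(unlist(glzlm_features(roi, connectivity = 6L)),
                 unlist(oracle_glzlm_features(roi, connectivity = 6L)),
                 tolerance = 1e-12)
    ng <- ngldm_features(roi)
    expect_equal(c(ng$contrast, ng$coarseness),
                 unlist(oracle_ngldm_features(roi), use.names = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("GLCM probabilities sum to 1 and run/zone normalizations close", {
  for (seed in 1:5) {
    roi <- make_random_roi(c(6, 6, 3), 5, seed + 100)
    expect_equal(sum(glcm_matrix(roi)$p), 1, tolerance = 1e-12)
    g <- glrlm_matrix(roi)
    expect_equal(sum(g$r) / g$n_runs, 1, tolerance = 1e-12)
    z <- glzlm_matrix(roi)
    expect_equal(sum(z$z) / z$n_zones, 1, tolerance = 1e-12)
  }
})

test_that("histogram features: uniform closed form, symmetry, moment oracle", {
  # 4 levels equally occupied
  vol <- voxel_volume(array(rep(0:3, 4), c(16, 1, 1)))
  msk <- roi_mask(array(1, c(16, 1, 1)))
  h <- histogram_features(vol, msk, n_bins = 4)
  expect_equal(h$energy_H, 0.25)
  expect_equal(h$entropy_H, 2)

  # symmetric distribution -> zero skewness
  sym <- c(-3, -1, 0, 0, 1, 3)
  vs <- voxel_volume(array(sym, c(6, 1, 1)))
  hs <- histogram_features(vs, roi_mask(array(1, c(6, 1, 1))), n_bins = 4)
  expect_equal(hs$skewness, 0, tolerance = 1e-14)

  set.seed(99)
  x <- rnorm(200)
  vo <- voxel_volume(array(x, c(200, 1, 1)))
  ho <- histogram_features(vo, roi_mask(array(1, c(200, 1, 1))))
  om <- oracle_moments(x)
  expect_equal(ho$skewness, om$skewness, tolerance = 1e-12)
  expect_equal(ho$kurtosis, om$kurtosis, tolerance = 1e-12)

  # constant ROI contract
  hc <- histogram_features(voxel_volume(array(5, c(4, 1, 1))),
                           roi_mask(array(1, c(4, 1, 1))))
  expect_true(is.na(hc$skewness) && is.na(hc$kurtosis))
  expect_equal(hc$entropy_H, 0)
  expect_equal(hc$energy_H, 1)
})

test_that("shape features: digitized ball near analytic sphere, box near closed form", {
  r <- 20; n <- 45; cx <- (n + 1) / 2
  co <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array((co$x - cx)^2 + (co$y - cx)^2 + (co$z - cx)^2 <= r^2,
                c(n, n, n))
  sf <- shape_features(roi_mask(ball))
  expect_gt(sf$sphericity, 0.96); expect_lt(sf$sphericity, 1.02)
  expect_lt(abs(sf$compacity - 1 / (6 * pi)) / (1 / (6 * pi)), 0.04)
  expect_true(sf$valid)

  bx <- array(FALSE, c(44, 24, 24)); bx[3:42, 3:22, 3:22] <- TRUE
  sb <- shape_features(roi_mask(bx))
  A_closed <- 2 * (40 * 20 + 20 * 20 + 20 * 40)
  expect_lt(abs(sb$surface_mm2 - A_closed) / A_closed, 0.05)
  expect_equal(sb$volume_mm3, 16000)
  expect_equal(sb$sphericity, pi^(1 / 3) * (6 * 16000)^(2 / 3) / sb$surface_mm2)

  sv <- shape_features(roi_mask(array(c(1, rep(0, 7)), c(2, 2, 2))))
  expect_false(sv$valid)
})

test_that("extractor reports every named feature with flags, deterministically", {
  set.seed(5)
  arr <- array(rnorm(6 * 6 * 4, 60, 12), c(6, 6, 4))
  m <- array(TRUE, c(6, 6, 4))
  vol <- voxel_volume(arr); msk <- roi_mask(m)
  fv <- extract_features(vol, msk, extract_config(n_bins = 8))
  expect_identical(names(fv$values), feature_names())
  expect_identical(names(fv$valid), feature_names())
  expect_true(all(!is.na(fv$values)))

  fv2 <- extract_features(vol, msk, extract_config(n_bins = 8))
  expect_identical(fv$values, fv2$values)

  # constant-intensity ROI: moments and correlation undefined, shape defined
  fvc <- extract_features(voxel_volume(array(3, c(4, 4, 3))),
                          roi_mask(array(1, c(4, 4, 3))))
  expect_false(fvc$valid[["skewness"]])
  expect_false(fvc$valid[["kurtosis"]])
  expect_false(fvc$valid[["glcm_correlation"]])
  expect_true(fvc$valid[["sphericity"]])
  expect_true(fvc$meta$degenerate_intensity)
})

test_that("feature-vector range invariants hold on random fixtures", {
  for (seed in 1:6) {
    set.seed(seed)
    arr <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
    m <- array(runif(75) < 0.8, c(5, 5, 3)); m[c(1, 2)] <- TRUE
    fv <- extract_features(voxel_volume(arr), roi_mask(m),
                           extract_config(n_bins = 6))
    v <- fv$values
    expect_true(v[["SRE"]] > 0 && v[["SRE"]] <= 1)
    expect_true(v[["SZE"]] > 0 && v[["SZE"]] <= 1)
    expect_true(v[["RP"]] > 0 && v[["RP"]] <= 1)
    expect_true(v[["ZP"]] > 0 && v[["ZP"]] <= 1)
    expect_true(v[["glcm_homogeneity"]] > 0 && v[["glcm_homogeneity"]] <= 1)
    expect_true(v[["glcm_energy"]] > 0 && v[["glcm_energy"]] <= 1)
    if (fv$valid[["glcm_correlation"]])
      expect_true(abs(v[["glcm_correlation"]]) <= 1 + 1e-12)
    expect_true(all(v[c("glcm_contrast", "glcm_dissimilarity",
                        "glcm_entropy", "ngldm_contrast")] >= 0))
    expect_true(all(v[c("GLNU_r", "RLNU", "GLNU_z", "ZLNU")] >= 1))
    expect_true(v[["compacity"]] > 0 && v[["sphericity"]] > 0)
  }
})
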