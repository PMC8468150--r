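ball_mask <- function(r, n = 2 * r + 4, spacing = c(1, 1, 1)) {
  co <- (seq_len(n) - 0.5 - n / 2)
  d2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  roi_mask(array(d2 <= r^2, dim = c(n, n, n)), spacing = spacing)
}
const_vol <- function(dims, value = 50) image_volume(array(value, dim = dims))

test_that("first-order statistics match hand arithmetic", {
  v <- image_volume(array(c(1, 2, 3, 0, 0, 0, 0, 0), dim = c(2, 2, 2)))
  m <- roi_mask(array(c(1, 1, 1, 0, 0, 0, 0, 0), dim = c(2, 2, 2)))
  f <- stats_features(v, m)
  expect_equal(unname(f["stats_mean"]), 2)
  expect_equal(unname(f["stats_energy"]), 14)
  expect_equal(unname(f["stats_range"]), 2)
  expect_equal(unname(f["stats_median"]), 2)
  expect_equal(unname(f["stats_var"]), 2 / 3)  # population variance
})

test_that("moments agree with an independent sample-moment oracle", {
  set.seed(123)
  x <- rnorm(1000, 50, 10)
  v <- image_volume(array(c(x, rep(0, 24)), dim = c(32, 32, 1)))
  m <- roi_mask(array(c(rep(1, 1000), rep(0, 24)), dim = c(32, 32, 1)))
  f <- stats_features(v, m)
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  expect_equal(unname(f["stats_mean"]), mu, tolerance = 1e-12)
  expect_equal(unname(f["stats_var"]), m2, tolerance = 1e-12)
  expect_equal(unname(f["stats_skewness"]), m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(unname(f["stats_kurtosis"]), m4 / m2^2 - 3, tolerance = 1e-12)
  expect_equal(unname(f["stats_rms"]), sqrt(mean(x^2)), tolerance = 1e-12)
})

test_that("constant ROIs give degenerate-case conventions", {
  v <- const_vol(c(3, 3, 3))
  m <- roi_mask(array(TRUE, dim = c(3, 3, 3)))
  f <- stats_features(v, m)
  expect_equal(unname(f["stats_var"]), 0)
  expect_equal(unname(f["stats_skewness"]), 0)
  b <- discretize(v, m)
  ih <- ih_features(b)
  expect_equal(unname(ih["ih_entropy"]), 0)
  expect_equal(unname(ih["ih_uniformity"]), 1)
  expect_equal(unname(ih["ih_var"]), 0)
})

test_that("histogram features are computed on the binned levels", {
  # levels 1,1,2,5 after binning 0,24,25,100 at width 25 (min anchor 0)
  v <- image_volume(array(c(0, 24, 25, 100, 0, 0, 0, 0), dim = c(2, 2, 2)))
  m <- roi_mask(array(c(1, 1, 1, 1, 0, 0, 0, 0), dim = c(2, 2, 2)))
  f <- ih_features(discretize(v, m))
  expect_equal(unname(f["ih_mode"]), 1)
  expect_equal(unname(f["ih_max"]), 5)
  expect_equal(unname(f["ih_mean"]), mean(c(1, 1, 2, 5)))
  p <- c(2, 1, 0, 0, 1) / 4
  expect_equal(unname(f["ih_uniformity"]), sum(p^2))
  expect_equal(unname(f["ih_entropy"]),
               -sum(p[p > 0] * log2(p[p > 0])))
})

test_that("voxel-count volume and centroid distance behave as defined", {
  arr <- array(FALSE, dim = c(14, 14, 14))
  arr[3:12, 3:12, 3:12] <- TRUE  # 10x10x10 cube
  m <- roi_mask(arr)
  f <- shape_features(m, const_vol(c(14, 14, 14)))
  expect_equal(unname(f["shape_vol_mm3"]), 1000)
  expect_equal(unname(f["shape_n_voxels"]), 1000)
  expect_equal(unname(f["shape_centroid_dist"]), 0)  # constant intensity
  expect_equal(unname(f["shape_bbox_vol"]), 1000)
  expect_equal(unname(f["shape_extent"]), 1)
  # an intensity gradient pulls the weighted centroid off the geometric one
  g <- coordgrid_volume(c(14, 14, 14))
  f2 <- shape_features(m, g)
  expect_gt(unname(f2["shape_centroid_dist"]), 0)
})

test_that("a digital ball approaches the analytic sphere", {
  m <- ball_mask(15, n = 64)
  f <- shape_features(m, const_vol(c(64, 64, 64)))
  expect_lt(abs(unname(f["shape_sphericity"]) - 1), 0.05)
  expect_lt(abs(unname(f["shape_max_diameter_3d"]) - 30), 1.5)
  expect_lt(abs(unname(f["shape_vol_mm3"]) / (4 / 3 * pi * 15^3) - 1), 0.05)
  expect_lt(abs(unname(f["shape_elongation"]) - 1), 0.05)
  expect_lt(abs(unname(f["shape_flatness"]) - 1), 0.05)
})

test_that("geometric shape features ignore intensities", {
  set.seed(21)
  arr <- array(runif(12^3) < 0.4, dim = c(12, 12, 12))
  arr[6, 6, 6] <- TRUE
  m <- roi_mask(arr)
  v1 <- image_volume(array(rnorm(12^3, 50, 20), dim = c(12, 12, 12)))
  v2 <- image_volume(array(rnorm(12^3, 120, 5), dim = c(12, 12, 12)))
  f1 <- shape_features(m, v1)
  f2 <- shape_features(m, v2)
  geo <- setdiff(names(f1), "shape_centroid_dist")
  expect_identical(f1[geo], f2[geo])
})

test_that("box-counting dimension hits the analytic limits", {
  solid <- roi_mask(array(TRUE, dim = c(64, 64, 64)))
  f <- fractal_features(solid)
  expect_lt(abs(unname(f["fractal_dim_mask"]) - 3), 0.2)

  slab <- array(FALSE, dim = c(64, 64, 3))
  slab[, , 2] <- TRUE
  f2 <- fractal_features(roi_mask(slab))
  expect_lt(abs(unname(f2["fractal_dim_mask"]) - 2), 0.2)
})

test_that("intensity peaks equal the intensity for uniform ROIs", {
  m <- ball_mask(8, n = 32)
  v <- const_vol(c(32, 32, 32), value = 77)
  f <- local_intensity_features(v, m)
  expect_equal(unname(f["locint_peak_local"]), 77, tolerance = 1e-9)
  expect_equal(unname(f["locint_peak_global"]), 77, tolerance = 1e-9)
})

test_that("a clipped peak sphere warns but still returns values", {
  m <- roi_mask(array(TRUE, dim = c(6, 6, 6)))
  v <- image_volume(array(rnorm(216, 50, 5), dim = c(6, 6, 6)))
  expect_warning(f <- local_intensity_features(v, m), "clipped")
  expect_true(all(is.finite(f)))
})

test_that("extract_all returns 167 deterministic finite features", {
  cfg <- cohort_config(n_patients = 1, n_lesions = 1, grid_size = 24,
                       lesion_radius_range = c(4, 7), seed = 31)
  cohort <- generate_cohort(cfg)
  f1 <- extract_all(cohort$volume[[1]], cohort$mask[[1]])
  f2 <- extract_all(cohort$volume[[1]], cohort$mask[[1]])
  expect_length(f1, 167)
  expect_true(all(is.finite(f1)))
  expect_identical(f1, f2)
  expect_identical(names(f1), feature_dictionary()$feature)
})

test_that("identical masks force identical geometric shape values", {
  cfg <- cohort_config(n_patients = 1, n_lesions = 1, grid_size = 24,
                       lesion_radius_range = c(4, 7), seed = 8)
  cohort <- generate_cohort(cfg)
  fa <- extract_all(cohort$volume[[1]], cohort$mask[[1]])
  fv <- extract_all(cohort$volume[[2]], cohort$mask[[2]])
  dict <- feature_dictionary()
  geo <- dict$feature[dict$family == "Shape" & !dict$intensity_dependent]
  expect_length(geo, 22)
  expect_identical(fa[geo], fv[geo])
  expect_false(identical(fa["stats_mean"], fv["stats_mean"]))
})
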