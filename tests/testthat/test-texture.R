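# Matrix builders against brute-force voxel-loop oracles, plus the spec'd
# hand-countable examples.

test_that("co-occurrence counts match exhaustive pair enumeration", {
  b <- make_binned(array(c(1, 1, 2, 2), dim = c(2, 2, 1)))
  counts <- glcm_matrix(b, normalize = FALSE)
  expect_same_counts(counts, oracle_glcm(b))
  # hand count: 4 voxels, all pairwise adjacent -> 12 ordered pairs
  expect_equal(sum(counts), 12)
})

test_that("all six texture matrices match brute force on random fixtures", {
  for (seed in 1:20) {
    b <- random_fixture(seed)
    expect_same_counts(glcm_matrix(b, normalize = FALSE), oracle_glcm(b))
    expect_same_counts(glrlm_matrix(b), oracle_glrlm(b))
    expect_same_counts(glszm_matrix(b), oracle_glszm(b))
    expect_same_counts(gldzm_matrix(b), oracle_gldzm(b))
    expect_same_counts(ngldm_matrix(b), oracle_ngldm(b))
    cmp <- ngtdm_components(b)
    orc <- oracle_ngtdm(b)
    expect_equal(cmp$n_i, orc$n_i)
    expect_equal(cmp$s_i, orc$s_i, tolerance = 1e-12)
  }
})

test_that("run counting matches manual enumeration on a line", {
  b <- make_binned(array(c(1, 1, 2, 2), dim = c(1, 1, 4)))
  R <- glrlm_matrix(b)
  # along the line direction: one length-2 run per level; each of the
  # other 12 directions sees every voxel as a unit run
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 2], 1)
  expect_equal(R[1, 1], 24)
  expect_equal(R[2, 1], 24)
  expect_equal(sum(R), 50)
  # every run accounted for: total run length x count = voxels x directions
  expect_equal(sum(R %*% seq_len(ncol(R))), 4 * 13)
})

test_that("a single connected zone is counted once at its size", {
  arr <- array(NA_integer_, dim = c(3, 3, 3))
  arr[c(1, 2, 5, 14, 27)] <- 1L  # 5 voxels, 26-connected through centre
  b <- make_binned(arr)
  S <- glszm_matrix(b)
  expect_equal(dim(S), c(1L, 5L))
  expect_equal(S[1, 5], 1)
  expect_equal(sum(S), 1)
})

test_that("every distance is 1 in a one-voxel-thick slab", {
  b <- make_binned(array(rep(1:2, 8), dim = c(4, 4, 1)))
  D <- gldzm_matrix(b)
  expect_equal(ncol(D), 1)  # all zones at distance 1
  d <- radphase:::chebyshev_distance_map(b$mask)
  expect_true(all(d[b$mask] == 1))
})

test_that("one-voxel stripes maximize merged-direction contrast", {
  # with all 26 neighbour offsets merged, alternating one-voxel slabs
  # separate 18 of 26 offsets (every offset moving along the stripe axis),
  # whereas the parity checkerboard separates only 14 (face diagonals
  # preserve parity) - so stripes dominate it and every random two-level
  # arrangement tried
  dims <- c(3, 3, 3)
  idx <- arrayInd(1:27, dims)
  contrast_of <- function(lev) {
    unname(glcm_features(make_binned(lev))["glcm_contrast"])
  }
  stripes <- array(1L + (idx[, 1] %% 2L), dim = dims)
  checker <- array(1L + (rowSums(idx) %% 2L), dim = dims)
  c_stripes <- contrast_of(stripes)
  expect_gt(c_stripes, contrast_of(checker))
  set.seed(99)
  best_random <- max(vapply(1:2000, function(i) {
    contrast_of(array(sample(c(1L, 2L), 27, replace = TRUE), dim = dims))
  }, numeric(1)))
  expect_gte(c_stripes, best_random)
})

test_that("merged-direction texture features are rotation invariant", {
  rotate90_z <- function(a) {
    # 90 degree rotation about the z axis
    aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  }
  b0 <- random_fixture(7)
  lev <- b0$levels
  levr <- rotate90_z(lev)
  f0 <- c(glcm_features(b0), glrlm_features(b0), glszm_features(b0),
          gldzm_features(b0), ngtdm_features(b0), ngldm_features(b0))
  br <- make_binned(levr)
  fr <- c(glcm_features(br), glrlm_features(br), glszm_features(br),
          gldzm_features(br), ngtdm_features(br), ngldm_features(br))
  expect_equal(f0, fr, tolerance = 1e-12)
})

test_that("normalized co-occurrence probabilities sum to one", {
  for (seed in c(2, 9, 31)) {
    b <- random_fixture(seed)
    P <- glcm_matrix(b)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(P, t(P))  # symmetry
  }
})

test_that("degenerate single-level ROIs give documented conventions", {
  b <- make_binned(array(1L, dim = c(3, 3, 3)))
  f <- glcm_features(b)
  expect_equal(unname(f["glcm_joint_max"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_correlation"]), 0)
  expect_true(all(is.finite(c(glrlm_features(b), glszm_features(b),
                              gldzm_features(b), ngtdm_features(b),
                              ngldm_features(b)))))
})
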