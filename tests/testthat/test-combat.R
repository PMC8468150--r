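# From-scratch empirical-Bayes ComBat: estimation, transform algebra,
# parameter recovery against the injection ground truth, and an
# independent-implementation cross-check.

test_that("fitting requires two batches with enough rows and variance", {
  tab <- gaussian_table(n_per_batch = 20, p = 5)
  one <- tab[tab$meta_batch == "arterial", ]
  expect_error(combat_fit(one), "at least 2 batches")

  small <- tab[c(1, 21, 22, 23), ]
  expect_error(combat_fit(small), "fewer than 2 rows")

  flat <- tab
  flat$f001 <- 5
  expect_error(combat_fit(flat), "f001")
})

test_that("null batch effects give near-zero shrunk estimates", {
  tab <- gaussian_table(n_per_batch = 500, p = 40, seed = 101)
  model <- combat_fit(tab)
  # gamma* ~ N(0, ~1/n) before shrinkage; shrinkage only tightens it
  expect_lt(max(abs(model$gamma_star)), 4 / sqrt(500))
  expect_lt(max(abs(model$delta_star2 - 1)), 5 * sqrt(2 / 500))
})

test_that("identity parameters leave the table unchanged", {
  tab <- gaussian_table(n_per_batch = 30, p = 8, seed = 5)
  model <- combat_fit(tab, eb = FALSE)
  model$gamma_star[] <- 0
  model$delta_star2[] <- 1
  out <- combat_transform(tab, model)
  expect_equal(as.matrix(out[feature_columns(out)]),
               as.matrix(tab[feature_columns(tab)]), tolerance = 1e-12)
})

test_that("transform equalizes batch means exactly without shrinkage", {
  tab <- gaussian_table(n_per_batch = 40, p = 12, seed = 31)
  spec <- batch_effect_spec(gamma = c(arterial = 0, venous = 5),
                            delta = c(arterial = 1, venous = 2),
                            eps_sd = 0.5, seed = 7)
  shifted <- inject_batch_effects(tab, spec)
  res <- combat_fit_transform(shifted, eb = FALSE)
  out <- res$table
  for (f in feature_columns(out)) {
    d <- mean(out[[f]][out$meta_batch == "arterial"]) -
      mean(out[[f]][out$meta_batch == "venous"])
    expect_lt(abs(d), 1e-10 * sd(out[[f]]))
  }
})

test_that("shrunk estimates recover injected ground truth", {
  tab <- gaussian_table(n_per_batch = 200, p = 60, seed = 13)
  set.seed(14)
  g_true <- rnorm(60, 0, 3)
  spec <- batch_effect_spec(
    gamma = list(arterial = 0, venous = g_true),
    delta = c(arterial = 1, venous = 1.5), eps_sd = 1, seed = 15)
  shifted <- inject_batch_effects(tab, spec)
  model <- combat_fit(shifted)
  est <- tidy(model)
  d <- est$gamma_star_data[est$batch == "venous"] -
    est$gamma_star_data[est$batch == "arterial"]
  expect_gt(cor(d, g_true), 0.99)
  # per-feature MC error: sd of a batch-mean difference ~ sqrt(2/n + 3.25/n)
  expect_lt(mean(abs(d - g_true)), 4 * sqrt((2 + 3.25) / 200))
})

test_that("EB shrinkage vanishes as the within-batch sample grows", {
  gaps <- vapply(c(5, 50, 500), function(n) {
    tab <- gaussian_table(n_per_batch = n, p = 30, seed = 1000 + n)
    spec <- batch_effect_spec(gamma = c(arterial = 0, venous = 2),
                              delta = c(arterial = 1, venous = 1),
                              eps_sd = 0.5, seed = 2)
    model <- combat_fit(inject_batch_effects(tab, spec))
    mean(abs(model$gamma_star - model$gamma_hat))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.02)
})

test_that("transform on duplicated batches is near-identity", {
  a <- gaussian_table(n_per_batch = 500, p = 50, seed = 3)
  a <- a[a$meta_batch == "arterial", ]
  b <- a
  b$meta_batch <- "venous"
  b$meta_patient_id <- paste0(b$meta_patient_id, "v")
  b$meta_lesion_id <- paste0(b$meta_lesion_id, "v")
  tab <- dplyr::bind_rows(a, b)
  out <- combat_fit_transform(tab)$table
  for (f in feature_columns(tab)) {
    expect_lt(max(abs(out[[f]] - tab[[f]])), 1e-2 * sd(tab[[f]]))
  }
})

test_that("re-fitting on harmonized data changes little", {
  tab <- gaussian_table(n_per_batch = 300, p = 40, seed = 8)
  set.seed(10)
  g_true <- rnorm(40, 0, 3)
  spec <- batch_effect_spec(gamma = list(arterial = 0, venous = g_true),
                            delta = c(arterial = 1, venous = 2),
                            eps_sd = 1, seed = 9)
  shifted <- inject_batch_effects(tab, spec)

  # a second pass re-processes only estimation noise (plus the
  # deterministic sqrt(n/(n-1)) scale convention): the typical (RMS)
  # change per feature stays below 1% of its sd, with or without
  # shrinkage
  for (use_eb in c(FALSE, TRUE)) {
    once <- combat_fit_transform(shifted, eb = use_eb)$table
    twice <- combat_fit_transform(once, eb = use_eb)$table
    for (f in feature_columns(tab)) {
      expect_lt(sqrt(mean((twice[[f]] - once[[f]])^2)),
                0.01 * sd(once[[f]]))
    }
  }
})

test_that("batch relabeling is symmetric", {
  tab <- gaussian_table(n_per_batch = 50, p = 10, seed = 12)
  spec <- batch_effect_spec(gamma = c(arterial = 0, venous = 2),
                            delta = c(arterial = 1, venous = 1.5),
                            eps_sd = 0.5, seed = 4)
  shifted <- inject_batch_effects(tab, spec)
  swapped <- shifted
  swapped$meta_batch <- ifelse(shifted$meta_batch == "arterial",
                               "venous", "arterial")
  out1 <- combat_fit_transform(shifted)$table
  out2 <- combat_fit_transform(swapped)$table
  expect_equal(as.matrix(out1[feature_columns(out1)]),
               as.matrix(out2[feature_columns(out2)]), tolerance = 1e-9)
})

test_that("covariate-predicted structure is preserved", {
  set.seed(44)
  n <- 200
  x <- rnorm(n)
  tab <- gaussian_table(n_per_batch = n / 2, p = 6, seed = 45)
  tab$cov_x <- x
  for (f in sprintf("f%03d", 1:6)) tab[[f]] <- tab[[f]] + 2 * x
  spec <- batch_effect_spec(gamma = c(arterial = 0, venous = 4),
                            delta = c(arterial = 1, venous = 1),
                            eps_sd = 0.5, seed = 46)
  feats <- sprintf("f%03d", 1:6)
  shifted <- tab
  shifted[feats] <- inject_batch_effects(
    tab[c(meta_columns(), feats)], spec)[feats]
  res <- combat_fit_transform(shifted, covariates = "cov_x")
  out <- res$table
  for (f in feats) {
    slope <- coef(lm(out[[f]] ~ x))[2]
    expect_lt(abs(slope - 2), 0.15)
  }
})

test_that("transform rejects unseen batches and missing features", {
  tab <- gaussian_table(n_per_batch = 20, p = 4, seed = 2)
  model <- combat_fit(tab)
  bad <- tab
  bad$meta_batch[1] <- "delayed"
  expect_error(combat_transform(bad, model), "unseen batch")
  expect_error(combat_transform(tab[-which(names(tab) == "f001")], model),
               "missing from table")
})

test_that("our ComBat matches the reference implementation", {
  skip_if_not_installed("sva")
  tab <- gaussian_table(n_per_batch = 40, p = 25, seed = 55)
  spec <- batch_effect_spec(gamma = c(arterial = 0, venous = 2),
                            delta = c(arterial = 1, venous = 1.6),
                            eps_sd = 0.8, seed = 56)
  shifted <- inject_batch_effects(tab, spec)
  ours <- combat_fit_transform(shifted)$table
  feats <- feature_columns(shifted)
  ref <- suppressMessages(sva::ComBat(
    dat = t(as.matrix(shifted[feats])),
    batch = shifted$meta_batch))
  expect_equal(as.matrix(ours[feats]), t(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("tidy and glance expose the fitted parameters", {
  tab <- gaussian_table(n_per_batch = 30, p = 7, seed = 61)
  model <- combat_fit(tab)
  td <- tidy(model)
  expect_equal(nrow(td), 2 * 7)
  expect_true(all(c("gamma_hat", "gamma_star", "delta_star2",
                    "gamma_star_data") %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$n_features, 7)
  expect_equal(gl$n_batches, 2)
  expect_true(gl$eb)
})
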