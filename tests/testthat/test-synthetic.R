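# Small cohort config used across tests: desk-scale but with the same
# structure as the default study conditions.
tiny_cohort <- function(seed = 1L, ...) {
  cohort_config(n_patients = 3, n_lesions = 4, grid_size = 24,
                lesion_radius_range = c(4, 7), seed = seed, ...)
}

test_that("cohorts are deterministic under the seed", {
  c1 <- generate_cohort(tiny_cohort(seed = 42))
  c2 <- generate_cohort(tiny_cohort(seed = 42))
  expect_identical(c1$volume[[1]]$voxels, c2$volume[[1]]$voxels)
  expect_identical(c1$mask[[3]]$voxels, c2$mask[[3]]$voxels)
  c3 <- generate_cohort(tiny_cohort(seed = 43))
  expect_false(identical(c1$volume[[1]]$voxels, c3$volume[[1]]$voxels))
})

test_that("each lesion has two phases sharing one identical mask", {
  cohort <- generate_cohort(tiny_cohort())
  expect_equal(nrow(cohort), 8)  # 4 lesions x 2 phases
  split_lesions <- split(cohort, cohort$lesion_id)
  for (les in split_lesions) {
    expect_setequal(les$phase, c("arterial", "venous"))
    expect_identical(les$mask[[1]]$voxels, les$mask[[2]]$voxels)
  }
})

test_that("zero noise and equal enhancement give identical phase volumes", {
  cfg <- tiny_cohort(noise_sd = 0,
                     arterial_enhancement = list(boost = 30,
                                                 heterogeneity = 15),
                     venous_enhancement = list(boost = 30,
                                               heterogeneity = 15))
  cohort <- generate_cohort(cfg)
  les <- cohort[cohort$lesion_id == "L001", ]
  expect_identical(les$volume[[1]]$voxels, les$volume[[2]]$voxels)
})

test_that("arterial lesions are brighter and more heterogeneous than venous", {
  cfg <- tiny_cohort(noise_sd = 0)
  cohort <- generate_cohort(cfg)
  for (lid in unique(cohort$lesion_id)) {
    les <- cohort[cohort$lesion_id == lid, ]
    m <- les$mask[[1]]$voxels
    art <- les$volume[[which(les$phase == "arterial")]]
    ven <- les$volume[[which(les$phase == "venous")]]
    expect_gt(mean(art$voxels[m]), mean(ven$voxels[m]))
    expect_gt(sd(art$voxels[m]), sd(ven$voxels[m]))
  }
})

test_that("the default configuration mirrors the 61/104 cohort scale", {
  cfg <- cohort_config()
  expect_equal(cfg$n_patients, 61L)
  expect_equal(cfg$n_lesions, 104L)
  plan <- radphase:::cohort_plan(cfg)
  expect_equal(nrow(plan), 104)
  expect_equal(length(unique(plan$patient_id)), 61)
  # 104 lesions -> 208 volumes and 104 distinct masks once generated
  expect_equal(nrow(plan) * 2, 208)
})

test_that("oversized lesions are rejected", {
  expect_error(cohort_config(grid_size = 16, lesion_radius_range = c(4, 20)),
               "larger than grid")
})

test_that("batch-effect injection follows the additive-multiplicative model", {
  set.seed(5)
  n <- 20
  tab <- tibble::tibble(
    meta_patient_id = sprintf("P%02d", 1:n),
    meta_lesion_id = sprintf("L%02d", 1:n),
    meta_batch = rep(c("a", "b"), each = n / 2),
    f1 = rnorm(n), f2 = rnorm(n, 10)
  )
  # identity parameters: output equals input
  spec0 <- batch_effect_spec(gamma = c(a = 0, b = 0), delta = c(a = 1, b = 1),
                             eps_sd = 0)
  expect_equal(inject_batch_effects(tab, spec0)[names(tab)], tab,
               ignore_attr = TRUE)

  # pure shift, no noise: batch-b means move by exactly 5
  spec5 <- batch_effect_spec(gamma = c(a = 0, b = 5), delta = c(a = 1, b = 1),
                             eps_sd = 0)
  out <- inject_batch_effects(tab, spec5)
  expect_equal(mean(out$f1[out$meta_batch == "b"]) -
                 mean(tab$f1[tab$meta_batch == "b"]), 5)
  expect_equal(out$f1[out$meta_batch == "a"], tab$f1[tab$meta_batch == "a"])
})

test_that("injected moments match the generative model at large n", {
  set.seed(6)
  n <- 1000
  tab <- tibble::tibble(
    meta_patient_id = sprintf("P%04d", 1:n),
    meta_lesion_id = sprintf("L%04d", 1:n),
    meta_batch = rep(c("a", "b"), each = n / 2),
    f1 = rnorm(n, 0, 1)
  )
  spec <- batch_effect_spec(gamma = c(a = 0, b = 3), delta = c(a = 1, b = 2),
                            eps_sd = 1, seed = 9)
  out <- inject_batch_effects(tab, spec)
  shift_b <- mean(out$f1[out$meta_batch == "b"] -
                    tab$f1[tab$meta_batch == "b"])
  expect_lt(abs(shift_b - 3), 4 * 2 / sqrt(n / 2))  # 4 MC standard errors
  resid_a <- out$f1[out$meta_batch == "a"] - tab$f1[tab$meta_batch == "a"]
  resid_b <- out$f1[out$meta_batch == "b"] - tab$f1[tab$meta_batch == "b"] - 3
  expect_lt(abs(sd(resid_b) / sd(resid_a) - 2), 0.3)
  truth <- batch_effect_truth(out)
  expect_equal(truth$gamma[truth$batch == "b"], 3)
  expect_equal(truth$delta[truth$batch == "b"], 2)
})

test_that("invalid batch-effect specs are rejected", {
  expect_error(batch_effect_spec(gamma = c(a = 0, b = 1),
                                 delta = c(a = 1, b = -2)), "> 0")
  expect_error(batch_effect_spec(gamma = c(a = 0), delta = c(a = 1)),
               "two or more")
  expect_error(batch_effect_spec(gamma = c(0, 1), delta = c(1, 1)),
               "named")
})
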