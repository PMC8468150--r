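#' Configuration for a synthetic paired-phase lesion cohort
#'
#' Describes a cohort of liver-lesion phantoms imaged in two
#' contrast-enhancement phases.  Each lesion is a randomly perturbed
#' superellipsoid carved into a noisy background grid; the arterial phase
#' adds a larger, more spatially heterogeneous intensity boost inside the
#' lesion than the portal venous phase, while both phases share one
#' identical segmentation mask — the situation in test–retest contrast-phase
#' studies where lesions are segmented once and the contour is copied to
#' both scans.
#'
#' Defaults mirror a 61-patient / 104-lesion contrast-phase cohort on a
#' desk-scale 64-voxel grid at 1 mm spacing, with lesion radii 4–20 mm.
#'
#' @param n_patients number of patients.
#' @param n_lesions total number of lesions across the cohort (each patient
#'   gets at least one while `n_lesions >= n_patients`).
#' @param grid_size voxels per axis (scalar, cubic grid).
#' @param spacing voxel spacing in mm (length 3 or scalar).
#' @param lesion_radius_range range (mm) the three lesion semi-axes are
#'   drawn from, uniformly.
#' @param background_hu list with `mean` (HU) and `sd` (between-patient
#'   baseline offset sd, HU).
#' @param arterial_enhancement,venous_enhancement lists with `boost` (mean
#'   HU added inside the lesion) and `heterogeneity` (sd, in HU, of the
#'   smoothed random enhancement field inside the lesion).
#' @param noise_sd per-voxel white-noise sd in HU (drawn independently per
#'   phase).
#' @param seed integer; fixes the whole cohort bit-for-bit.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 61L,
                          n_lesions = 104L,
                          grid_size = 64L,
                          spacing = c(1, 1, 1),
                          lesion_radius_range = c(4, 20),
                          background_hu = list(mean = 50, sd = 8),
                          arterial_enhancement = list(boost = 60,
                                                      heterogeneity = 25),
                          venous_enhancement = list(boost = 20,
                                                    heterogeneity = 10),
                          noise_sd = 10,
                          seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(n_patients >= 1, n_lesions >= 1, grid_size >= 8,
            length(lesion_radius_range) == 2,
            lesion_radius_range[1] > 0,
            diff(lesion_radius_range) >= 0,
            noise_sd >= 0,
            all(spacing > 0))
  max_diam <- 2 * lesion_radius_range[2]
  if (max_diam + 4 * max(spacing) > grid_size * min(spacing)) {
    stop("lesion larger than grid: maximum diameter ", max_diam,
         " mm does not fit a ", grid_size, "-voxel grid at ",
         min(spacing), " mm spacing", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_lesions = as.integer(n_lesions),
                 grid_size = as.integer(grid_size),
                 spacing = as.numeric(spacing),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 background_hu = background_hu,
                 arterial_enhancement = arterial_enhancement,
                 venous_enhancement = venous_enhancement,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic per-lesion plan: patient assignment, patient baseline
# offsets and one RNG seed per lesion, all derived from the master seed so
# that lesions can be generated independently (and lazily) in any order.
cohort_plan <- function(config) {
  set.seed(config$seed)
  np <- config$n_patients
  nl <- config$n_lesions
  patient_offset <- stats::rnorm(np, 0, config$background_hu$sd)
  if (nl >= np) {
    pat <- c(seq_len(np), sample(np, nl - np, replace = TRUE))
  } else {
    pat <- sample(np, nl)
  }
  pat <- sort(pat)
  lesion_seed <- sample.int(.Machine$integer.max - 1L, nl)
  tibble::tibble(
    patient_id = sprintf("P%03d", pat),
    lesion_id = sprintf("L%03d", seq_len(nl)),
    patient_offset = patient_offset[pat],
    lesion_seed = lesion_seed
  )
}

# Generate one lesion: a shared mask and the two phase volumes.
# RNG draws happen in a fixed order (shape field, enhancement field,
# arterial noise, venous noise) so the realization is reproducible from the
# lesion seed alone.
generate_lesion <- function(config, lesion_seed, patient_offset) {
  set.seed(lesion_seed)
  n <- config$grid_size
  sp <- config$spacing
  dims <- c(n, n, n)
  rr <- config$lesion_radius_range
  radii <- stats::runif(3, rr[1], rr[2])
  p <- stats::runif(1, 2, 2.5)
  extent_mm <- dims * sp
  slack <- pmax(0, extent_mm / 2 - radii - 2 * sp)
  centre <- extent_mm / 2 + stats::runif(3, -1, 1) * pmin(slack, 5)

  # implicit superellipsoid + low-frequency radial perturbation
  margin <- ceiling(max(radii) / min(sp)) + 3L
  cvox <- pmin(pmax(round(centre / sp) + 1L, 1L), dims)
  rng <- lapply(1:3, function(k) {
    max(1L, cvox[k] - margin):min(dims[k], cvox[k] + margin)
  })
  bdims <- vapply(rng, length, integer(1))
  gx <- (rng[[1]] - 1) * sp[1]
  gy <- (rng[[2]] - 1) * sp[2]
  gz <- (rng[[3]] - 1) * sp[3]
  X <- array(rep(gx, times = bdims[2] * bdims[3]), dim = bdims)
  Y <- array(rep(rep(gy, each = bdims[1]), times = bdims[3]), dim = bdims)
  Z <- array(rep(gz, each = bdims[1] * bdims[2]), dim = bdims)
  f <- (abs(X - centre[1]) / radii[1])^p +
    (abs(Y - centre[2]) / radii[2])^p +
    (abs(Z - centre[3]) / radii[3])^p
  w <- gaussian_smooth3(array(stats::rnorm(prod(bdims)), dim = bdims), 2)
  w <- (w - mean(w)) / max(stats::sd(w), 1e-12)
  inside_box <- f + 0.15 * w <= 1
  inside_box[ceiling(bdims[1] / 2), ceiling(bdims[2] / 2),
             ceiling(bdims[3] / 2)] <- TRUE  # centre voxel always inside
  mask_arr <- array(FALSE, dim = dims)
  mask_arr[rng[[1]], rng[[2]], rng[[3]]] <- inside_box

  # shared enhancement heterogeneity field, zero mean / unit sd in-mask
  h <- gaussian_smooth3(array(stats::rnorm(prod(bdims)), dim = bdims), 3)
  hv <- h[inside_box]
  if (length(hv) > 1 && stats::sd(hv) > 0) {
    h <- (h - mean(hv)) / stats::sd(hv)
  } else {
    h[] <- 0
  }
  het_field <- array(0, dim = dims)
  het_field[rng[[1]], rng[[2]], rng[[3]]] <- h

  base <- config$background_hu$mean + patient_offset
  make_phase <- function(enh) {
    vol <- array(base, dim = dims)
    if (config$noise_sd > 0) {
      vol <- vol + stats::rnorm(prod(dims), 0, config$noise_sd)
    } else {
      stats::rnorm(1)  # keep the RNG stream aligned across noise settings
    }
    vol[mask_arr] <- vol[mask_arr] + enh$boost +
      enh$heterogeneity * het_field[mask_arr]
    image_volume(vol, spacing = sp)
  }
  arterial <- make_phase(config$arterial_enhancement)
  venous <- make_phase(config$venous_enhancement)
  list(mask = roi_mask(mask_arr, spacing = sp),
       arterial = arterial, venous = venous)
}

#' Generate a synthetic paired-phase cohort
#'
#' For each lesion, two [image_volume()]s (phases `"arterial"` and
#' `"venous"`) share one identical [roi_mask()].  The output is fully
#' deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A tibble with one row per volume (two per lesion): columns
#'   `patient_id`, `lesion_id`, `phase`, and list-columns `volume`
#'   ([image_volume()]) and `mask` ([roi_mask()]; the same object for both
#'   phases of a lesion).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 2, n_lesions = 2,
#'                                         grid_size = 24,
#'                                         lesion_radius_range = c(4, 7)))
#' nrow(cohort)  # 2 lesions x 2 phases
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  plan <- cohort_plan(config)
  rows <- purrr::pmap(plan, function(patient_id, lesion_id, patient_offset,
                                     lesion_seed) {
    les <- generate_lesion(config, lesion_seed, patient_offset)
    tibble::tibble(
      patient_id = patient_id,
      lesion_id = lesion_id,
      phase = c("arterial", "venous"),
      volume = list(les$arterial, les$venous),
      mask = list(les$mask, les$mask)
    )
  })
  dplyr::bind_rows(rows)
}

#' Specification of feature-level batch effects
#'
#' Describes the additive/multiplicative batch distortion model
#' `Y'_ij = Y_ij + gamma_i + delta_i * eps_ij`, `eps ~ N(0, eps_sd^2)`,
#' used to forward-simulate batch effects on a feature table with known
#' ground truth.
#'
#' @param gamma named numeric vector: additive shift per batch label (one
#'   value per batch, applied to every feature), or a named list of
#'   per-feature vectors.
#' @param delta named numeric vector of multiplicative noise scales per
#'   batch (strictly positive).
#' @param eps_sd sd of the error term (before scaling by `delta`).
#' @param seed integer RNG seed for the error draws.
#' @return An object of class `batch_effect_spec`.
#' @export
batch_effect_spec <- function(gamma, delta, eps_sd = 1, seed = 1L) {
  if (is.null(names(gamma)) || is.null(names(delta))) {
    stop("`gamma` and `delta` must be named by batch label", call. = FALSE)
  }
  if (!setequal(names(gamma), names(delta))) {
    stop("`gamma` and `delta` must cover the same batch labels",
         call. = FALSE)
  }
  if (length(delta) < 2L) stop("need two or more batches", call. = FALSE)
  if (any(unlist(delta) <= 0)) {
    stop("multiplicative batch effects `delta` must be > 0", call. = FALSE)
  }
  if (eps_sd < 0) stop("`eps_sd` must be >= 0", call. = FALSE)
  structure(list(gamma = gamma, delta = unlist(delta), eps_sd = eps_sd,
                 seed = as.integer(seed)),
            class = "batch_effect_spec")
}

#' Inject known batch effects into a feature table
#'
#' Forward-simulates the ComBat generative model: every feature value in
#' batch `i` becomes `Y + gamma_i + delta_i * eps`, with `eps` drawn i.i.d.
#' `N(0, eps_sd^2)`.  The ground truth used is attached as attribute
#' `"batch_truth"` (a tibble) for recovery tests; retrieve it with
#' [batch_effect_truth()].
#'
#' @param table a feature table (see [as_feature_table()]).
#' @param spec a [batch_effect_spec()] whose batch labels cover the table's
#'   `meta_batch` values.
#' @return The distorted feature table (same shape, metadata untouched).
#' @export
inject_batch_effects <- function(table, spec) {
  table <- as_feature_table(table)
  stopifnot(inherits(spec, "batch_effect_spec"))
  feats <- feature_columns(table)
  batches <- unique(table$meta_batch)
  missing_b <- setdiff(batches, names(spec$delta))
  if (length(missing_b)) {
    stop("spec does not cover batch label(s): ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  }
  if (any(table(table$meta_batch) < 2)) {
    stop("each batch needs at least 2 rows", call. = FALSE)
  }
  set.seed(spec$seed)
  out <- table
  for (b in batches) {
    rows <- which(table$meta_batch == b)
    g <- spec$gamma[[b]]
    if (length(g) == 1L) g <- rep(g, length(feats))
    if (length(g) != length(feats)) {
      stop("per-feature gamma for batch ", b, " has length ", length(g),
           ", expected ", length(feats), call. = FALSE)
    }
    eps <- matrix(stats::rnorm(length(rows) * length(feats), 0, spec$eps_sd),
                  nrow = length(rows))
    shift <- matrix(g, nrow = length(rows), ncol = length(feats),
                    byrow = TRUE)
    out[rows, feats] <- table[rows, feats] + shift + spec$delta[[b]] * eps
  }
  truth <- purrr::map_dfr(batches, function(b) {
    g <- spec$gamma[[b]]
    if (length(g) == 1L) g <- rep(g, length(feats))
    tibble::tibble(batch = b, feature = feats, gamma = g,
                   delta = spec$delta[[b]], eps_sd = spec$eps_sd)
  })
  attr(out, "batch_truth") <- truth
  out
}

#' Ground-truth batch effects attached by [inject_batch_effects()]
#' @param table a table returned by [inject_batch_effects()].
#' @return tibble with columns `batch`, `feature`, `gamma`, `delta`,
#'   `eps_sd`.
#' @export
batch_effect_truth <- function(table) {
  truth <- attr(table, "batch_truth")
  if (is.null(truth)) {
    stop("no batch ground truth attached to this table", call. = FALSE)
  }
  truth
}
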