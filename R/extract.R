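#' Feature dictionary: the 167 features and their 11 families
#'
#' One row per feature, in extraction order, with the family tag and a flag
#' marking features that depend on voxel intensities (as opposed to the
#' mask geometry alone).  Family cardinalities are Fractal 3, GLCM 26,
#' GLDZM 16, GLRLM 15, GLSZM 16, IH 25, LocInt 2, NGLDM 17, NGTDM 5,
#' Shape 23, Stats 19.  Within families the dictionary follows the IBSI
#' reference definitions, with documented extras or omissions where the
#' published family counts differ from IBSI's (GLCM adds the maximal
#' correlation coefficient; GLRLM omits normalized gray-level
#' non-uniformity; IH adds the 25th/75th percentiles; Stats adds the
#' standard deviation).
#'
#' @return tibble with columns `feature`, `family`, `intensity_dependent`.
#' @export
feature_dictionary <- function() {
  fd <- function(features, family, intensity = TRUE) {
    tibble::tibble(feature = features, family = family,
                   intensity_dependent = intensity)
  }
  shape_names <- names(shape_features(.unit_mask(), .unit_volume()))
  dplyr::bind_rows(
    fd(names(stats_features(.unit_volume(), .unit_mask())), "Stats"),
    fd(names(ih_features(.unit_binned())), "IH"),
    fd(names(suppressWarnings(
      local_intensity_features(.unit_volume(), .unit_mask()))), "LocInt"),
    fd(shape_names, "Shape",
       intensity = shape_names == "shape_centroid_dist"),
    fd(names(fractal_features(.unit_mask())), "Fractal", intensity = FALSE),
    fd(names(glcm_features(.unit_binned())), "GLCM"),
    fd(names(glrlm_features(.unit_binned())), "GLRLM"),
    fd(names(glszm_features(.unit_binned())), "GLSZM"),
    fd(names(gldzm_features(.unit_binned())), "GLDZM"),
    fd(names(ngtdm_features(.unit_binned())), "NGTDM"),
    fd(names(ngldm_features(.unit_binned())), "NGLDM")
  )
}

# Tiny cached fixtures used only to enumerate feature names.
.unit_cache <- new.env(parent = emptyenv())
.unit_volume <- function() {
  if (is.null(.unit_cache$vol)) {
    .unit_cache$vol <- image_volume(array(seq_len(27), dim = c(3, 3, 3)))
  }
  .unit_cache$vol
}
.unit_mask <- function() {
  if (is.null(.unit_cache$mask)) {
    .unit_cache$mask <- roi_mask(array(1, dim = c(3, 3, 3)))
  }
  .unit_cache$mask
}
.unit_binned <- function() {
  if (is.null(.unit_cache$binned)) {
    .unit_cache$binned <- suppressWarnings(
      discretize(.unit_volume(), .unit_mask(), bin_width = 10))
  }
  .unit_cache$binned
}

#' Extract all 167 radiomic features from one ROI
#'
#' Runs every family on an (image, mask) pair after fixed-bin-width
#' discretization of the in-mask intensities.  The result is deterministic
#' and finite for any mask with at least one voxel (degenerate
#' constant-intensity ROIs use documented convention values).
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param bin_width discretization bin width in HU (default 25).
#' @return named numeric vector of 167 features, in the order of
#'   [feature_dictionary()].
#' @export
extract_all <- function(volume, mask, bin_width = 25) {
  binned <- discretize(volume, mask, bin_width = bin_width)
  out <- c(
    stats_features(volume, mask),
    ih_features(binned),
    suppressWarnings(local_intensity_features(volume, mask)),
    shape_features(mask, volume),
    fractal_features(mask),
    glcm_features(binned),
    glrlm_features(binned),
    glszm_features(binned),
    gldzm_features(binned),
    ngtdm_features(binned),
    ngldm_features(binned)
  )
  stopifnot(length(out) == 167L)
  out
}

#' Extract features for every ROI of a cohort
#'
#' Applies [extract_all()] to each row of a cohort tibble (as produced by
#' [generate_cohort()]) and assembles a feature table with metadata
#' columns.
#'
#' @param cohort tibble with columns `patient_id`, `lesion_id`, `phase`
#'   and list-columns `volume`, `mask`.
#' @param bin_width discretization bin width in HU.
#' @return A feature table tibble: `meta_patient_id`, `meta_lesion_id`,
#'   `meta_batch` (the phase) and 167 feature columns.
#' @export
extract_cohort_features <- function(cohort, bin_width = 25) {
  stopifnot(all(c("patient_id", "lesion_id", "phase", "volume", "mask")
                %in% names(cohort)))
  feats <- purrr::map(seq_len(nrow(cohort)), function(i) {
    extract_all(cohort$volume[[i]], cohort$mask[[i]],
                bin_width = bin_width)
  })
  as_feature_table(dplyr::bind_cols(
    tibble::tibble(meta_patient_id = cohort$patient_id,
                   meta_lesion_id = cohort$lesion_id,
                   meta_batch = cohort$phase),
    tibble::as_tibble(do.call(rbind, feats))
  ))
}
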