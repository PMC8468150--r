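#' Configuration for the end-to-end reproducibility pipeline
#'
#' Bundles the cohort description with the analysis constants: the
#' discretization bin width (25 HU), the CCC reproducibility cutoff (0.9),
#' the near-zero-variance modal-frequency threshold (0.95) and the
#' volume-correlation cutoff (0.85).
#'
#' @param cohort a [cohort_config()]; its seed drives the whole run.
#' @param bin_width discretization bin width in HU.
#' @param ccc_cutoff reproducibility threshold on the CCC.
#' @param nzv_threshold near-zero-variance modal-frequency threshold.
#' @param volume_r_cutoff volume-correlation threshold on `|r|`.
#' @param seed optional override of the cohort seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            bin_width = 25,
                            ccc_cutoff = 0.9,
                            nzv_threshold = 0.95,
                            volume_r_cutoff = 0.85,
                            seed = NULL) {
  stopifnot(inherits(cohort, "cohort_config"),
            bin_width > 0,
            ccc_cutoff >= -1, ccc_cutoff <= 1,
            nzv_threshold > 0, nzv_threshold <= 1,
            volume_r_cutoff >= 0, volume_r_cutoff <= 1)
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, bin_width = bin_width,
                 ccc_cutoff = ccc_cutoff, nzv_threshold = nzv_threshold,
                 volume_r_cutoff = volume_r_cutoff),
            class = "pipeline_config")
}

#' Run the full contrast-phase reproducibility analysis
#'
#' Executes: generate the paired-phase cohort, extract the 167 features per
#' ROI per phase, compute the CCC of every feature across phases, remove
#' shape and near-zero-variance features, harmonize the remainder with
#' ComBat (phase as batch, no covariates), recompute the CCC, classify
#' every feature, and assess volume correlation before and after
#' harmonization.  Deterministic under the config seed.
#'
#' Lesions are generated and extracted one at a time so peak memory stays
#' small even for large cohorts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return An object of class `repro_report`: a list with `features` (one
#'   row per feature: family, CCC before/after, flags, class), `table`
#'   (the extracted feature table), `harmonized` (the harmonized table),
#'   `model` (the `combat_model`), `config`, and `class_counts`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[radphase] ", ...)
  cc <- config$cohort
  plan <- cohort_plan(cc)
  say("cohort: ", cc$n_patients, " patients, ", cc$n_lesions,
      " lesions on a ", cc$grid_size, "^3 grid")

  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    les <- generate_lesion(cc, plan$lesion_seed[i], plan$patient_offset[i])
    fa <- extract_all(les$arterial, les$mask, bin_width = config$bin_width)
    fv <- extract_all(les$venous, les$mask, bin_width = config$bin_width)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(meta_patient_id = rep(plan$patient_id[i], 2),
                     meta_lesion_id = rep(plan$lesion_id[i], 2),
                     meta_batch = c("arterial", "venous")),
      tibble::as_tibble(rbind(fa, fv))
    )
  }
  table <- as_feature_table(dplyr::bind_rows(rows))
  say("extracted ", length(feature_columns(table)), " features x ",
      nrow(table), " ROIs")

  dict <- feature_dictionary()
  arterial <- batch_rows(table, "arterial")
  venous <- batch_rows(table, "venous")
  before <- screen_features(arterial, venous, cutoff = config$ccc_cutoff)
  say(sum(before$reproducible), " features with CCC > ",
      config$ccc_cutoff, " before harmonization")

  # near-zero variance by modal frequency; features constant within a
  # phase are equally degenerate (no estimable within-batch scale, hence
  # nothing ComBat can harmonize) and join the same exclusion class
  nzv <- vapply(feature_columns(table), function(f) {
    near_zero_variance(table[[f]], threshold = config$nzv_threshold) ||
      any(tapply(table[[f]], table$meta_batch, stats::var) == 0)
  }, logical(1))
  is_shape <- dict$family == "Shape"
  harmonizable <- dict$feature[!is_shape & !nzv[dict$feature]]
  say(length(harmonizable), " features enter ComBat (",
      sum(is_shape), " shape and ", sum(nzv[dict$feature] & !is_shape),
      " near-zero-variance features excluded)")

  sub <- table[c(meta_columns(), harmonizable)]
  fitted <- combat_fit_transform(sub, batch = "meta_batch")
  after <- screen_features(batch_rows(fitted$table, "arterial"),
                           batch_rows(fitted$table, "venous"),
                           cutoff = config$ccc_cutoff)
  say(sum(after$reproducible), " features with CCC > ",
      config$ccc_cutoff, " after harmonization")

  vc_before <- suppressWarnings(
    volume_correlation(table, cutoff = config$volume_r_cutoff))
  vol_tbl_after <- fitted$table
  vol_tbl_after$shape_vol_mm3 <- table$shape_vol_mm3
  vc_after <- suppressWarnings(
    volume_correlation(vol_tbl_after, candidates = harmonizable,
                       cutoff = config$volume_r_cutoff))

  features <- dict %>%
    dplyr::left_join(dplyr::rename(before, ccc_before = "ccc",
                                   reproducible_before = "reproducible"),
                     by = "feature") %>%
    dplyr::left_join(
      dplyr::select(dplyr::rename(after, ccc_after = "ccc",
                                  reproducible_after = "reproducible"),
                    "feature", "ccc_after", "reproducible_after"),
      by = "feature") %>%
    dplyr::mutate(
      near_zero_variance = unname(nzv[.data$feature]),
      delta_ccc = .data$ccc_after - .data$ccc_before,
      class = dplyr::case_when(
        .data$family == "Shape" ~ "shape_excluded_from_combat",
        .data$near_zero_variance ~ "nzv_removed",
        .data$reproducible_before & .data$reproducible_after ~
          "always_reproducible",
        !.data$reproducible_before & .data$reproducible_after ~
          "gained_by_combat",
        .data$reproducible_before & !.data$reproducible_after ~
          "lost_by_combat",
        TRUE ~ "never_reproducible"
      )
    ) %>%
    dplyr::left_join(
      dplyr::rename(vc_before, pearson_r_volume = "pearson_r_with_volume"),
      by = "feature") %>%
    dplyr::left_join(
      dplyr::rename(vc_after,
                    pearson_r_volume_harmonized = "pearson_r_with_volume",
                    volume_correlated_harmonized = "volume_correlated"),
      by = "feature")

  structure(list(features = features,
                 table = table,
                 harmonized = fitted$table,
                 model = fitted$model,
                 config = config,
                 class_counts = table(features$class)),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("<repro_report> ", nrow(x$features), " features, ",
      x$config$cohort$n_lesions, " lesions x 2 phases\n", sep = "")
  cc <- as.list(x$class_counts)
  for (k in names(cc)) cat(sprintf("  %-28s %d\n", k, cc[[k]]))
  invisible(x)
}

#' Histogram of CCC changes under harmonization
#'
#' Bins the per-feature change `ccc_after - ccc_before` of the harmonized
#' features into the conventional reporting bands: a decrement, gains of
#' `[0, 0.1)`, `[0.1, 0.5)`, `[0.5, 0.6)`, and `>= 0.6`.
#'
#' @param report a `repro_report` from [run_pipeline()].
#' @return tibble with columns `band` and `n`; the counts sum to the
#'   number of harmonized features.
#' @export
summarize_delta <- function(report) {
  stopifnot(inherits(report, "repro_report"))
  d <- report$features$delta_ccc
  d <- d[!is.na(d)]
  bands <- c("(-Inf,0)", "[0,0.1)", "[0.1,0.5)", "[0.5,0.6)", "[0.6,Inf)")
  cut_d <- cut(d, breaks = c(-Inf, 0, 0.1, 0.5, 0.6, Inf), right = FALSE,
               labels = bands)
  tibble::tibble(band = bands,
                 n = as.integer(table(cut_d)[bands]))
}

#' Write a reproducibility report to disk
#'
#' Writes `report.csv` (the per-feature table), `summary.txt`
#' (human-readable class and family counts plus the config snapshot) and,
#' optionally, `ccc_before_after.pdf` (the [plot_ccc_comparison()] figure).
#'
#' @param report a `repro_report`.
#' @param dir output directory (created if needed).
#' @param figure also write the CCC scatter figure (default `TRUE`).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir, figure = TRUE) {
  stopifnot(inherits(report, "repro_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  feats <- report$features
  num <- vapply(feats, is.numeric, logical(1))
  out <- feats
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, file.path(dir, "report.csv"), progress = FALSE)

  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c("radphase reproducibility report", ""), con)
  writeLines("Features per class:", con)
  for (k in names(report$class_counts)) {
    writeLines(sprintf("  %-28s %d", k, report$class_counts[[k]]), con)
  }
  writeLines(c("", "Reproducible features per family (before / after):"),
             con)
  fam <- feats %>%
    dplyr::group_by(.data$family) %>%
    dplyr::summarise(
      n = dplyr::n(),
      before = sum(.data$reproducible_before, na.rm = TRUE),
      after = sum(.data$reproducible_after, na.rm = TRUE))
  for (i in seq_len(nrow(fam))) {
    writeLines(sprintf("  %-8s n=%-3d %d / %d", fam$family[i], fam$n[i],
                       fam$before[i], fam$after[i]), con)
  }
  writeLines(c("", "Config:"), con)
  cfg <- report$config
  writeLines(sprintf("  bin_width=%g ccc_cutoff=%g nzv_threshold=%g volume_r_cutoff=%g",
                     cfg$bin_width, cfg$ccc_cutoff, cfg$nzv_threshold,
                     cfg$volume_r_cutoff), con)
  writeLines(sprintf("  cohort: n_patients=%d n_lesions=%d grid=%d seed=%d",
                     cfg$cohort$n_patients, cfg$cohort$n_lesions,
                     cfg$cohort$grid_size, cfg$cohort$seed), con)

  if (figure) {
    p <- plot_ccc_comparison(report)
    grDevices::pdf(file.path(dir, "ccc_before_after.pdf"), width = 7,
                   height = 5)
    print(p)
    grDevices::dev.off()
  }
  invisible(dir)
}

#' Read back the per-feature table of a written report
#' @param dir directory written by [write_report()].
#' @return tibble equal to `report$features` of the originating report.
#' @export
read_report <- function(dir) {
  path <- file.path(dir, "report.csv")
  if (!file.exists(path)) stop("no report.csv in ", dir, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    feature = readr::col_character(),
                    family = readr::col_character(),
                    class = readr::col_character(),
                    intensity_dependent = readr::col_logical(),
                    near_zero_variance = readr::col_logical(),
                    reproducible_before = readr::col_logical(),
                    reproducible_after = readr::col_logical(),
                    volume_correlated = readr::col_logical(),
                    volume_correlated_harmonized = readr::col_logical(),
                    .default = readr::col_double()))
}
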