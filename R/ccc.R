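#' Lin's concordance correlation coefficient
#'
#' Measures agreement between paired measurements as
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`, with all
#' moments computed with 1/n denominators (Lin's original estimator, no
#' small-sample bias correction).  Identical constant vectors return 1 by
#' convention — agreement is perfect even though the ratio is 0/0; constant
#' but unequal vectors return 0.
#'
#' @param x,y equal-length numeric vectors of paired values (aligned by
#'   subject), `n >= 3`, all finite.
#' @return a single value in `[-1, 1]`.
#' @export
#' @examples
#' ccc(1:4, 1:4)          # 1
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
ccc <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs, got ", n, call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in `x` or `y`", call. = FALSE)
  }
  mx <- mean(x)
  my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) return(1)  # identical constant vectors
  2 * sxy / denom
}

#' Near-zero-variance flag
#'
#' `TRUE` when the most frequent value accounts for at least
#' `threshold` of the observations (exact bit equality of doubles; ties on
#' the modal value do not matter since only its count is used).
#'
#' @param values numeric vector, `n >= 1`.
#' @param threshold modal-frequency cutoff (default 0.95).
#' @return logical flag.
#' @export
near_zero_variance <- function(values, threshold = 0.95) {
  stopifnot(length(values) >= 1)
  modal <- max(tabulate(match(values, unique(values))))
  modal / length(values) >= threshold
}

#' Pearson correlation of candidate features with volume
#'
#' Flags features whose absolute Pearson correlation with the volume
#' feature exceeds `cutoff` (volume surrogates).  The absolute value is
#' used so strongly negative surrogates are flagged too.  Zero-variance
#' candidates have undefined correlation: they are returned with `NA`
#' values and a warning.
#'
#' @param table a feature table.
#' @param volume_feature name of the volume column (default
#'   `"shape_vol_mm3"`).
#' @param candidates feature names to test (default: all features except
#'   the volume feature itself is kept in, so the self-correlation of 1 is
#'   visible).
#' @param cutoff flag threshold on `|r|` (default 0.85).
#' @return tibble with columns `feature`, `pearson_r_with_volume`,
#'   `volume_correlated`.
#' @export
volume_correlation <- function(table, volume_feature = "shape_vol_mm3",
                               candidates = NULL, cutoff = 0.85) {
  table <- as_feature_table(table)
  if (!volume_feature %in% names(table)) {
    stop("volume feature `", volume_feature, "` not found", call. = FALSE)
  }
  if (is.null(candidates)) candidates <- feature_columns(table)
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  v <- table[[volume_feature]]
  r <- vapply(candidates, function(f) {
    x <- table[[f]]
    if (stats::sd(x) == 0 || stats::sd(v) == 0) return(NA_real_)
    stats::cor(x, v)
  }, numeric(1))
  degenerate <- candidates[is.na(r)]
  if (length(degenerate)) {
    warning("zero-variance candidate(s) with undefined correlation: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(feature = candidates,
                 pearson_r_with_volume = unname(r),
                 volume_correlated = abs(unname(r)) > cutoff)
}

#' Screen paired-phase feature tables with Lin's CCC
#'
#' Pairs the rows of the two tables strictly by (patient, lesion), computes
#' the CCC of every shared feature across the pair, and flags features with
#' `ccc > cutoff` as reproducible.
#'
#' @param table_a,table_b feature tables for the two phases; every
#'   (patient, lesion) must appear in both (unmatched ROIs are an error).
#' @param cutoff reproducibility threshold on the CCC (default 0.9,
#'   strict inequality).
#' @return tibble with columns `feature`, `ccc`, `n_pairs`,
#'   `reproducible`.
#' @export
screen_features <- function(table_a, table_b, cutoff = 0.9) {
  table_a <- as_feature_table(table_a)
  table_b <- as_feature_table(table_b)
  key_a <- paste(table_a$meta_patient_id, table_a$meta_lesion_id, sep = "/")
  key_b <- paste(table_b$meta_patient_id, table_b$meta_lesion_id, sep = "/")
  if (anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stop("duplicate (patient, lesion) rows within a phase", call. = FALSE)
  }
  only_a <- setdiff(key_a, key_b)
  only_b <- setdiff(key_b, key_a)
  if (length(only_a) || length(only_b)) {
    stop("unmatched ROI(s) across phases: ",
         paste(c(only_a, only_b), collapse = ", "), call. = FALSE)
  }
  ord <- match(key_a, key_b)
  feats <- intersect(feature_columns(table_a), feature_columns(table_b))
  vals <- vapply(feats, function(f) {
    ccc(table_a[[f]], table_b[[f]][ord])
  }, numeric(1))
  tibble::tibble(feature = feats, ccc = unname(vals),
                 n_pairs = length(key_a),
                 reproducible = unname(vals) > cutoff)
}
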