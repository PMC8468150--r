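#' @importFrom rlang .data
NULL

# Metadata columns carried by every feature table.  The "meta_" prefix makes
# the metadata/feature split unambiguous: every other column is a feature.
meta_columns <- function() c("meta_patient_id", "meta_lesion_id", "meta_batch")

#' Validate a feature table
#'
#' A feature table holds one row per ROI per phase: the metadata columns
#' `meta_patient_id`, `meta_lesion_id` and `meta_batch` (the phase / batch
#' label) followed by named numeric feature columns.
#'
#' @param table a data frame.
#' @return the table as a tibble, invisibly validated.
#' @export
as_feature_table <- function(table) {
  table <- tibble::as_tibble(table)
  missing_meta <- setdiff(meta_columns(), names(table))
  if (length(missing_meta)) {
    stop("feature table is missing metadata column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(table))) {
    stop("duplicate column names: ",
         paste(unique(names(table)[duplicated(names(table))]),
               collapse = ", "), call. = FALSE)
  }
  feats <- feature_columns(table)
  bad <- feats[!vapply(table[feats], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  table
}

#' Names of the feature columns of a feature table
#' @param table a feature table.
#' @return character vector of feature names (everything that is not a
#'   `meta_` column).
#' @export
feature_columns <- function(table) {
  setdiff(names(table), grep("^meta_", names(table), value = TRUE))
}

#' Write a feature table to CSV at full precision
#'
#' Numeric values are serialized with 17 significant digits so that
#' write-then-read round-trips reproduce every double bit-for-bit.  Column
#' and row order are preserved.
#'
#' @param table a feature table (see [as_feature_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- as_feature_table(table)
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path with a header; must contain the `meta_` metadata
#'   columns (duplicate or missing columns are errors, never repaired
#'   silently).
#' @return a tibble feature table in file order.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  hdr <- gsub('^"|"$', "", hdr)
  if (anyDuplicated(hdr)) {
    stop("duplicate feature names in ", path, ": ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "), call. = FALSE)
  }
  if (!"meta_batch" %in% hdr) {
    stop("missing batch_label column `meta_batch` in ", path, call. = FALSE)
  }
  # read numerics as text and convert via strtod (correctly rounded), so
  # the %.17g serialization round-trips bit-for-bit
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  feats <- setdiff(names(tab), grep("^meta_", names(tab), value = TRUE))
  tab[feats] <- lapply(tab[feats], as.numeric)
  as_feature_table(tab)
}

# Feature-table rows for one batch label, in table order.
batch_rows <- function(table, label) {
  dplyr::filter(table, .data$meta_batch == label)
}

# n x p numeric matrix of the feature columns.
feature_matrix <- function(table, features = feature_columns(table)) {
  as.matrix(table[features])
}
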