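#' Scatter plot of per-feature CCC before versus after harmonization
#'
#' One point per harmonized feature, coloured by family, with the
#' reproducibility cutoff drawn on both axes and the identity line for
#' reference.  Points above the diagonal gained concordance under
#' harmonization.
#'
#' @param report a `repro_report` from [run_pipeline()].
#' @return a ggplot object.
#' @export
plot_ccc_comparison <- function(report) {
  stopifnot(inherits(report, "repro_report"))
  cutoff <- report$config$ccc_cutoff
  df <- dplyr::filter(report$features, !is.na(.data$ccc_after))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ccc_before,
                                   y = .data$ccc_after,
                                   colour = .data$family)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::geom_point(alpha = 0.8, size = 2) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "CCC before harmonization",
                  y = "CCC after harmonization",
                  colour = "Family",
                  title = "Cross-phase concordance before vs after ComBat") +
    ggplot2::theme_minimal()
}

#' Histogram of per-feature CCC values by phase comparison
#'
#' @param report a `repro_report`.
#' @param which `"before"` (default) or `"after"`.
#' @return a ggplot object.
#' @export
plot_ccc_distribution <- function(report, which = c("before", "after")) {
  which <- match.arg(which)
  stopifnot(inherits(report, "repro_report"))
  col <- paste0("ccc_", which)
  df <- report$features[!is.na(report$features[[col]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[col]], fill = .data$family)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0) +
    ggplot2::geom_vline(xintercept = report$config$ccc_cutoff,
                        linetype = "dashed") +
    ggplot2::labs(x = paste("CCC", which, "harmonization"), y = "Features",
                  fill = "Family") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for reproducibility reports
#' @param object a `repro_report`.
#' @param ... passed on (unused).
#' @return a ggplot object ([plot_ccc_comparison()]).
#' @export
autoplot.repro_report <- function(object, ...) {
  plot_ccc_comparison(object)
}
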