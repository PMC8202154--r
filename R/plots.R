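#' Calibration plot of biological versus chronological age
#'
#' Mean biological age per chronological-age bin against the bin-mean
#' chronological age; the dashed identity line is perfect calibration.
#'
#' @param report A `bioage_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_calibration <- function(report, ...) {
  df <- purrr::map_dfr(report$strata, function(st) {
    dplyr::mutate(st$calibration, sex = st$sex)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_ca, y = .data$mean_ba,
                                   colour = .data$sex)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Mean chronological age in bin (years)",
                  y = "Mean biological age (years)",
                  colour = "Sex",
                  title = "Calibration of biological age") +
    ggplot2::theme_minimal()
}

#' Importance of components in the biological age
#'
#' Bar chart of the share of biological-age variance carried by each of the
#' top components, labelled by their primary biomarker.
#'
#' @param report A `bioage_report`.
#' @param top_n Number of components to display per sex.
#' @return A ggplot object.
#' @export
plot_importance <- function(report, top_n = 15) {
  df <- purrr::map_dfr(report$strata, function(st) {
    lab <- st$components$characterization
    dplyr::slice_head(st$importance, n = top_n) |>
      dplyr::left_join(lab[, c("component", "label")], by = "component") |>
      dplyr::mutate(sex = st$sex,
                    name = paste0(.data$component, " (", .data$label, ")"))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$name, .data$share),
                                   y = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~sex, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Share of biological-age variance",
                  title = "Component importance in the biological age") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by age-acceleration group
#'
#' Outcome-free survival for participants whose biological age is at least
#' 5 years younger than, similar to, or at least 5 years older than their
#' chronological age.
#'
#' @param report A `bioage_report`.
#' @param outcome Name of the outcome to plot (default first configured).
#' @return A ggplot object.
#' @export
plot_km_acceleration <- function(report, outcome = NULL) {
  outcome <- outcome %||% names(report$config$outcomes)[1]
  df <- purrr::map_dfr(report$strata, function(st) {
    dplyr::mutate(st$evaluations[[outcome]]$km, sex = st$sex)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Years since baseline", y = "Outcome-free survival",
                  colour = "BA vs CA",
                  title = sprintf("Survival by age-acceleration group (%s)", outcome)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_calibration
#' @param object A `bioage_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.bioage_report <- function(object, ...) {
  plot_calibration(object, ...)
}
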