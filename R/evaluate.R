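#' Evaluate biological versus chronological age for one outcome
#'
#' Runs the full comparison for one sex stratum and one right-censored
#' outcome: nested Cox partial log-likelihoods (null, CA-only, BA-only,
#' BA + CA), the proportion of the combined age effect explained by BA,
#' likelihood-ratio tests for adding BA to CA, Harrell's C-indices
#' (unadjusted and, if `covariates` is non-empty, covariate-adjusted),
#' Kaplan-Meier curves across +/- `acceleration_threshold`-year
#' age-acceleration groups, and the log-rank test across those groups.
#'
#' @param data Data frame for the stratum, containing `ba_col`, `ca_col`,
#'   the outcome columns, and any adjustment covariates.
#' @param ba_col,ca_col Column names of biological and chronological age.
#' @param time,event Outcome column names (years; 0/1).
#' @param covariates Adjustment covariate columns (may be empty).
#' @param acceleration_threshold Years defining younger/older groups.
#' @return Object of class `bioage_eval` with elements `loglik` (tibble),
#'   `proportion_explained`, `lrt` (BA added to CA), `c_indices` (tibble),
#'   `km` (tibble of curves), `log_rank`, `acceleration_fractions`, and
#'   bookkeeping (`n`, `n_events`).
#' @export
evaluate_outcome <- function(data, ba_col = "ba", ca_col = "ca",
                             time, event, covariates = character(),
                             acceleration_threshold = 5) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) abort("empty risk set", class = "bioage_empty_risk_set")

  fit_null <- fit_cox(data, time, event, character())
  fit_ca <- fit_cox(data, time, event, ca_col)
  fit_ba <- fit_cox(data, time, event, ba_col)
  fit_both <- fit_cox(data, time, event, c(ba_col, ca_col))

  ll <- tibble::tibble(
    model = c("null", "ca", "ba", "both"),
    loglik = c(fit_null$ll, fit_ca$ll, fit_ba$ll, fit_both$ll)
  )
  # numerical jitter guard: nesting must hold up to tiny slack
  check_nested_lls(ll)

  prop <- proportion_explained(fit_null$ll, fit_ba$ll, fit_both$ll)
  lrt <- likelihood_ratio_test(fit_ca, fit_both)

  tt <- data[[time]]
  ev <- data[[event]]
  c_un <- dplyr::bind_rows(
    dplyr::mutate(harrells_c(data[[ca_col]], tt, ev), predictor = "ca"),
    dplyr::mutate(harrells_c(data[[ba_col]], tt, ev), predictor = "ba"),
    dplyr::mutate(harrells_c(fit_both$linear_predictor, tt, ev), predictor = "ba_ca")
  ) |> dplyr::mutate(adjusted = FALSE)
  c_tab <- c_un
  if (length(covariates)) {
    c_adj <- dplyr::bind_rows(
      dplyr::mutate(adjusted_c(data, ca_col, covariates, time, event), predictor = "ca"),
      dplyr::mutate(adjusted_c(data, ba_col, covariates, time, event), predictor = "ba"),
      dplyr::mutate(adjusted_c(data, c(ba_col, ca_col), covariates, time, event),
                    predictor = "ba_ca")
    ) |> dplyr::mutate(adjusted = TRUE)
    c_tab <- dplyr::bind_rows(c_un, c_adj)
  }
  c_tab <- dplyr::relocate(c_tab, "predictor", "adjusted")

  acc <- age_acceleration_groups(data[[ba_col]], data[[ca_col]],
                                 acceleration_threshold)
  km <- kaplan_meier(tt, ev, acc$group)
  lr <- log_rank(tt, ev, acc$group)

  structure(
    list(
      loglik = ll, proportion_explained = prop, lrt = lrt,
      c_indices = c_tab, km = km, log_rank = lr,
      acceleration_fractions = acc$fractions,
      n = nrow(data), n_events = sum(ev),
      time = time, event = event
    ),
    class = "bioage_eval"
  )
}

check_nested_lls <- function(ll, slack = 1e-6) {
  v <- setNames(ll$loglik, ll$model)
  ok <- v["both"] >= max(v["ca"], v["ba"]) - slack && min(v["ca"], v["ba"]) >= v["null"] - slack
  if (!ok) abort("nested log-likelihood ordering violated in evaluation")
  invisible(TRUE)
}

#' @export
print.bioage_eval <- function(x, ...) {
  cat(sprintf("Evaluation (%s): %d events / %d subjects\n", x$event, x$n_events, x$n))
  cat(sprintf("  proportion of combined age effect explained by BA: %s\n",
              ifelse(is.na(x$proportion_explained), "NA",
                     sprintf("%.3f", x$proportion_explained))))
  cat(sprintf("  LRT for adding BA to CA: chi^2 = %.2f (df %d), p = %.3g\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p_value))
  print(x$c_indices)
  invisible(x)
}
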