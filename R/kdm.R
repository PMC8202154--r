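#' Per-component age regressions
#'
#' Ordinary least squares of each component score on chronological age over
#' the fit subset: `score_j = q_j + k_j * ca + e`, with residual RMSE `s_j`
#' (denominator n - 2). These linear associations with age are the inputs
#' the Klemera-Doubal estimator inverts.
#'
#' @param scores Data frame / matrix of component scores (fit rows).
#' @param ca Chronological ages (years) for the same rows.
#' @return A tibble with `component`, `q` (intercept), `k` (slope per year),
#'   `s` (residual RMSE), `n_fit`, and `informative` (FALSE when |k| or `s`
#'   is numerically degenerate).
#' @export
fit_age_regressions <- function(scores, ca) {
  x <- as.matrix(scores)
  n <- nrow(x)
  if (n < 3) abort("age regressions need at least 3 fit rows")
  if (var(ca) == 0) abort("chronological age has zero variance on the fit rows")
  ca_c <- ca - mean(ca)
  sxx <- sum(ca_c^2)
  k <- as.vector(crossprod(ca_c, x)) / sxx
  q <- colMeans(x) - k * mean(ca)
  resid <- x - outer(rep(1, n), q) - outer(ca, k)
  s <- sqrt(colSums(resid^2) / (n - 2))
  tibble::tibble(
    component = colnames(x) %||% paste0("PC", seq_along(k)),
    q = unname(q), k = unname(k), s = unname(s), n_fit = n,
    informative = abs(k) > 1e-12 & s > 1e-12
  )
}

#' Fit a Klemera-Doubal biological-age model
#'
#' Builds the KDM estimator from per-component age regressions, without
#' chronological age as a constituent biomarker. The biological age of a
#' score profile `x` is
#' `BA = sum_j (x_j - q_j) k_j / s_j^2 / sum_j k_j^2 / s_j^2`,
#' equivalently a weighted combination with weights
#' `w_j = (k_j / s_j^2) / sum_i k_i^2 / s_i^2` satisfying
#' `sum_j w_j k_j = 1` (calibration consistency: profiles lying exactly on
#' their regression lines at age a give BA = a). Components with
#' numerically zero slope are dropped with a warning; they contribute no
#' age signal and would leave their weights undefined.
#'
#' @param scores Data frame of component scores on the fit rows (typically
#'   the healthy subset of one sex).
#' @param ca Chronological age (years) of the fit rows.
#' @param sex Optional label (`"M"`/`"F"`) carried into the model.
#' @param ca_correction If `TRUE`, fit the CA-corrected Klemera-Doubal
#'   variant, which shrinks BA towards CA using
#'   `s_BA^2 = max(Var(BA - CA) - 1/denom, 0)` where `1/denom` is the
#'   propagated measurement variance of the uncorrected estimator. The
#'   default (`FALSE`) is the uncorrected estimator without CA as a
#'   biomarker, so BA can be compared against CA downstream.
#' @return Object of class `bioage_kdm`: `regressions` tibble (with weight
#'   column `w`), `sex`, fit diagnostics `r_squared` (of BA vs CA on the fit
#'   rows) and `ba_sd_diff` (SD of BA - CA), plus the fit-subset score
#'   variances used for importance.
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 500, seed = 3))
#' cm <- fit_components(cohort, grep("^bm", names(cohort), value = TRUE))
#' km <- fit_kdm(cm$scores, cohort$ca)
#' glance(km)
#' @export
fit_kdm <- function(scores, ca, sex = NA_character_, ca_correction = FALSE) {
  reg <- fit_age_regressions(scores, ca)
  usable <- reg$informative
  if (!any(usable)) abort("no usable components: all age-regression slopes are degenerate")
  if (any(!usable)) {
    warn(sprintf("dropping %d non-informative component(s): %s",
                 sum(!usable), paste(reg$component[!usable], collapse = ", ")))
  }
  denom <- sum(reg$k[usable]^2 / reg$s[usable]^2)
  reg$w <- ifelse(usable, (reg$k / reg$s^2) / denom, 0)

  model <- structure(
    list(
      regressions = reg, sex = sex, denom = denom,
      ca_correction = FALSE, s_ba2 = NA_real_,
      score_variances = apply(as.matrix(scores), 2, var)
    ),
    class = "bioage_kdm"
  )
  ba_fit <- compute_ba(scores, model)
  model$r_squared <- ba_r_squared(ba_fit, ca)
  model$ba_sd_diff <- sd(ba_fit - ca)
  if (ca_correction) {
    model$ca_correction <- TRUE
    model$s_ba2 <- max(var(ba_fit - ca) - 1 / denom, 0)
    ba_fit <- compute_ba(scores, model, ca = ca)
    model$r_squared <- ba_r_squared(ba_fit, ca)
    model$ba_sd_diff <- sd(ba_fit - ca)
  }
  model
}

#' Compute biological age from component scores
#'
#' @param scores Data frame / matrix of component scores, columns matching
#'   the model's components.
#' @param model A fitted [fit_kdm()] model.
#' @param ca Chronological ages; required only for a `ca_correction` model.
#' @return Numeric vector of biological ages (years), one per row.
#' @export
compute_ba <- function(scores, model, ca = NULL) {
  stopifnot(inherits(model, "bioage_kdm"))
  reg <- model$regressions
  use <- reg$informative
  x <- as.matrix(as.data.frame(scores)[, reg$component[use], drop = FALSE])
  num <- as.vector(sweep(x, 2, reg$q[use]) %*% (reg$k[use] / reg$s[use]^2))
  if (isTRUE(model$ca_correction)) {
    if (is.null(ca)) abort("`ca` is required for a CA-corrected KDM model")
    if (model$s_ba2 <= 0) return(ca)  # zero-variance limit: BA collapses to CA
    return((num + ca / model$s_ba2) / (model$denom + 1 / model$s_ba2))
  }
  num / model$denom
}

#' @rdname compute_ba
#' @param object A `bioage_kdm` model.
#' @param newdata Data frame of component scores.
#' @param ... Unused.
#' @export
predict.bioage_kdm <- function(object, newdata, ca = NULL, ...) {
  compute_ba(newdata, object, ca = ca)
}

#' Squared correlation of biological with chronological age
#'
#' @param ba,ca Numeric vectors (years).
#' @return Squared Pearson correlation, or `NA` when either input has zero
#'   variance.
#' @export
ba_r_squared <- function(ba, ca) {
  if (length(ba) < 2 || var(ba) == 0 || var(ca) == 0) return(NA_real_)
  cor(ba, ca)^2
}

#' Component importance in the biological age
#'
#' Decomposes the variance of BA over components:
#' `share_j = w_j^2 Var(score_j) / Var(BA)`. With pairwise-uncorrelated
#' scores the shares are exact variance fractions and sum to 1; they equal
#' the marginal R-squared of BA on each score.
#'
#' @param model A fitted [fit_kdm()] model.
#' @param score_variances Optional named per-component variances; defaults
#'   to the fit-subset variances stored in the model.
#' @return Tibble `component`, `share`, `rank`, sorted by descending share.
#' @export
component_importance <- function(model, score_variances = NULL) {
  stopifnot(inherits(model, "bioage_kdm"))
  reg <- model$regressions
  v <- score_variances %||% model$score_variances
  v <- v[reg$component]
  contrib <- reg$w^2 * v
  share <- contrib / sum(contrib)
  out <- tibble::tibble(component = reg$component, share = unname(share))
  out <- dplyr::arrange(out, dplyr::desc(.data$share))
  out$rank <- seq_len(nrow(out))
  out
}

#' Calibration of biological age against chronological age
#'
#' Mean BA and mean CA per chronological-age bin (left-closed bins of
#' `bin_width` years starting at the youngest configured age). Empty bins
#' are omitted.
#'
#' @param ba,ca Numeric vectors (years).
#' @param bin_width Bin width in years.
#' @param origin Left edge of the first bin; defaults to `floor(min(ca))`.
#' @return Tibble `bin_start`, `bin_end`, `n`, `mean_ca`, `mean_ba`.
#' @export
calibration_table <- function(ba, ca, bin_width = 2.5, origin = NULL) {
  origin <- origin %||% floor(min(ca))
  bin <- origin + bin_width * floor((ca - origin) / bin_width)
  tibble::tibble(bin_start = bin, ba = ba, ca = ca) |>
    dplyr::group_by(.data$bin_start) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ca = mean(.data$ca),
      mean_ba = mean(.data$ba),
      .groups = "drop"
    ) |>
    dplyr::mutate(bin_end = .data$bin_start + bin_width, .after = "bin_start") |>
    dplyr::arrange(.data$bin_start)
}

#' Age-acceleration groups
#'
#' Classifies each participant by BA - CA: at least `threshold` years
#' younger (`BA - CA <= -threshold`), at least `threshold` years older
#' (`BA - CA >= threshold`), or similar. Boundaries are closed ("at least
#' 5 years").
#'
#' @param ba,ca Numeric vectors (years).
#' @param threshold Years; default 5.
#' @return A list with `group` (factor `younger`/`similar`/`older` per row)
#'   and `fractions` (tibble of group fractions).
#' @export
age_acceleration_groups <- function(ba, ca, threshold = 5) {
  diff <- ba - ca
  group <- factor(
    dplyr::case_when(
      diff <= -threshold ~ "younger",
      diff >= threshold ~ "older",
      TRUE ~ "similar"
    ),
    levels = c("younger", "similar", "older")
  )
  frac <- as.vector(prop.table(table(group)))
  fractions <- tibble::tibble(
    group = factor(levels(group), levels(group)),
    fraction = frac
  )
  list(group = group, fractions = fractions)
}

#' @export
print.bioage_kdm <- function(x, ...) {
  cat(sprintf(
    "Klemera-Doubal biological age (%s): %d components (%d informative)\n",
    ifelse(is.na(x$sex), "unstratified", x$sex),
    nrow(x$regressions), sum(x$regressions$informative)
  ))
  cat(sprintf("  R^2 vs chronological age: %.3f; SD(BA - CA): %.2f years\n",
              x$r_squared, x$ba_sd_diff))
  invisible(x)
}
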