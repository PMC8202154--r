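#' Fit a Cox proportional-hazards model
#'
#' Thin wrapper over [survival::coxph()] (Efron tie handling by default)
#' returning the quantities the evaluation stage compares: the maximized
#' partial log-likelihood, the null (beta = 0) partial log-likelihood, and
#' the linear predictor. An empty covariate set gives the null model.
#'
#' @param data Data frame with one row per subject.
#' @param time,event Column names (strings) of the follow-up time (years,
#'   > 0) and 0/1 event indicator.
#' @param covariates Character vector of covariate column names (possibly
#'   empty). Character/factor columns enter as factors.
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return Object of class `bioage_cox`: `coefficients`, `ll` (at the MLE),
#'   `ll_null`, `n`, `n_events`, `linear_predictor`, `converged`, and the
#'   underlying `coxph` fit (`NULL` for the null model).
#' @export
fit_cox <- function(data, time, event, covariates = character(),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  data <- as.data.frame(data)
  tt <- data[[time]]
  ev <- data[[event]]
  if (nrow(data) == 0) abort("empty risk set", class = "bioage_empty_risk_set")
  if (any(tt <= 0)) abort("all follow-up times must be > 0")
  if (sum(ev) < 1) abort("at least one event is required", class = "bioage_empty_risk_set")

  if (length(covariates) == 0) {
    # null model: partial likelihood at beta = 0
    f0 <- survival::coxph(
      survival::Surv(tt, ev) ~ 1, data = data, ties = ties
    )
    return(structure(
      list(coefficients = numeric(), ll = f0$loglik[1], ll_null = f0$loglik[1],
           n = nrow(data), n_events = sum(ev),
           linear_predictor = rep(0, nrow(data)), converged = TRUE,
           covariates = character(), fit = NULL),
      class = "bioage_cox"
    ))
  }

  d2 <- data
  d2$.time_ <- tt
  d2$.event_ <- ev
  fml <- stats::reformulate(covariates, response = "survival::Surv(.time_, .event_)")
  fit <- survival::coxph(fml, data = d2, ties = ties)
  cf <- coef(fit)
  structure(
    list(
      coefficients = cf,
      ll = fit$loglik[2], ll_null = fit$loglik[1],
      n = fit$n, n_events = fit$nevent,
      linear_predictor = unname(fit$linear.predictors),
      converged = all(is.finite(cf)) && all(abs(cf) < 15),
      covariates = covariates, fit = fit
    ),
    class = "bioage_cox"
  )
}

#' Proportion of the combined age effect explained by biological age
#'
#' Compares nested Cox partial log-likelihoods: the share of the combined
#' BA + CA log-likelihood gain over the null model attained by BA alone,
#' `(ll_ba - ll_null) / (ll_both - ll_null)`.
#'
#' @param ll_null,ll_ba,ll_both Partial log-likelihoods of the null model,
#'   the BA-only model, and the BA + CA model on the same rows.
#' @param slack Numerical slack allowed on the nesting order.
#' @return The fraction, or `NA` when the combined gain is below `slack`.
#' @export
proportion_explained <- function(ll_null, ll_ba, ll_both, slack = 1e-8) {
  if (ll_ba < ll_null - slack || ll_both < ll_ba - slack) {
    abort("log-likelihood ordering violated (ll_both >= ll_ba >= ll_null expected); upstream fit suspect")
  }
  denom <- ll_both - ll_null
  if (denom < slack) return(NA_real_)
  (ll_ba - ll_null) / denom
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param fit_reduced,fit_full `bioage_cox` fits on the same rows, with the
#'   reduced model's covariates a subset of the full model's.
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_reduced, fit_full) {
  if (!all(fit_reduced$covariates %in% fit_full$covariates)) {
    abort("models are not nested: reduced covariates must be a subset of full")
  }
  if (fit_reduced$n != fit_full$n) abort("models are fit on different rows")
  stat <- max(2 * (fit_full$ll - fit_reduced$ll), 0)
  df <- length(fit_full$coefficients) - length(fit_reduced$coefficients)
  tibble::tibble(
    statistic = stat, df = df,
    # df = 0 means identical models: no evidence against the reduced fit
    p_value = if (df > 0) pchisq(stat, df, lower.tail = FALSE) else 1
  )
}

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs (the earlier time is an observed
#' event) in which the subject with the earlier event carries the higher
#' risk score; tied scores score 0.5, pairs tied on time with both events
#' are incomparable (standard Harrell convention). Computed via
#' [survival::concordance()].
#'
#' @param risk_scores Numeric vector; higher must mean higher risk (CA and
#'   BA are used directly as risk scores).
#' @param times,events Follow-up times and 0/1 event indicators.
#' @return The C-index as a tibble `c_index`, `se`, `n_pairs`; `c_index` is
#'   `NA` when no pair is comparable.
#' @export
harrells_c <- function(risk_scores, times, events) {
  df <- data.frame(s = risk_scores, t = times, e = events)
  cc <- survival::concordance(survival::Surv(t, e) ~ s, data = df, reverse = TRUE)
  counts <- cc$count
  n_pairs <- sum(counts[c("concordant", "discordant", "tied.x")])
  tibble::tibble(
    c_index = if (n_pairs == 0) NA_real_ else unname(cc$concordance),
    se = if (n_pairs == 0) NA_real_ else sqrt(cc$var),
    n_pairs = unname(n_pairs)
  )
}

#' Covariate-adjusted concordance of an age predictor
#'
#' Fits a Cox model on the age predictor plus adjustment covariates
#' (deprivation quintile, smoking, alcohol, assessment center in the
#' canonical analysis) and reports Harrell's C of the full linear
#' predictor.
#'
#' @param data Data frame.
#' @param predictors Character vector: the age column(s) (e.g. `"ba"` or
#'   `c("ba", "ca")`).
#' @param covariates Character vector of adjustment covariate columns.
#' @inheritParams fit_cox
#' @return Tibble `c_index`, `se`, `n_pairs`.
#' @export
adjusted_c <- function(data, predictors, covariates, time, event) {
  keep <- covariates[vapply(covariates, function(cv) {
    v <- data[[cv]]
    length(unique(v)) > 1
  }, logical(1))]
  fit <- fit_cox(data, time, event, c(predictors, keep))
  harrells_c(fit$linear_predictor, data[[time]], data[[event]])
}

#' Kaplan-Meier curves by group
#'
#' Product-limit survival estimates per group, returned as a tidy step-curve
#' table.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param groups Factor/character grouping (e.g. age-acceleration group).
#' @return Tibble `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
kaplan_meier <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) abort("empty group in Kaplan-Meier input")
  df <- data.frame(t = times, e = events, g = groups)
  sf <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  strata <- if (is.null(sf$strata)) {
    rep(levels(groups)[1], length(sf$time))
  } else {
    rep(sub("^g=", "", names(sf$strata)), sf$strata)
  }
  tibble::tibble(
    group = factor(strata, levels(groups)),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    survival = sf$surv
  )
}

#' Log-rank test across groups
#'
#' Observed-versus-expected event counts summed over event times;
#' chi-square with `groups - 1` degrees of freedom.
#'
#' @inheritParams kaplan_meier
#' @return Tibble `statistic`, `df`, `p_value`; all `NA` when there are no
#'   events.
#' @export
log_rank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) abort("empty group in log-rank input")
  if (sum(events) == 0) {
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  }
  df_ <- data.frame(t = times, e = events, g = groups)
  sd_ <- survival::survdiff(survival::Surv(t, e) ~ g, data = df_)
  df <- length(sd_$n) - 1
  tibble::tibble(
    statistic = sd_$chisq, df = df,
    p_value = pchisq(sd_$chisq, df, lower.tail = FALSE)
  )
}

#' Benchmark mortality score by stepwise Cox regression
#'
#' Forward-stepwise selection over component scores against the mortality
#' outcome: at each step the candidate with the smallest likelihood-ratio
#' p-value enters if p < `p_enter`; after each entry, any selected component
#' whose removal p-value exceeds `p_remove` is dropped. The final linear
#' predictor is the benchmark score that biomarker ages are compared
#' against.
#'
#' @param data Data frame containing the score columns and outcome.
#' @param components Character vector of candidate score columns.
#' @inheritParams fit_cox
#' @param p_enter,p_remove Entry / removal p-value thresholds.
#' @return List `selected` (character), `score` (linear predictor per row;
#'   all zero when nothing enters), `fit` (`bioage_cox` or `NULL`).
#' @export
stepwise_mortality_score <- function(data, components, time, event,
                                     p_enter = 0.05, p_remove = 0.10) {
  selected <- character()
  repeat {
    changed <- FALSE
    candidates <- setdiff(components, selected)
    if (length(candidates)) {
      fit_cur <- fit_cox(data, time, event, selected)
      pvals <- vapply(candidates, function(cv) {
        likelihood_ratio_test(fit_cur, fit_cox(data, time, event, c(selected, cv)))$p_value
      }, numeric(1))
      if (min(pvals) < p_enter) {
        selected <- c(selected, candidates[which.min(pvals)])
        changed <- TRUE
      }
    }
    if (length(selected) > 1) {
      fit_cur <- fit_cox(data, time, event, selected)
      drop_p <- vapply(selected, function(cv) {
        likelihood_ratio_test(fit_cox(data, time, event, setdiff(selected, cv)), fit_cur)$p_value
      }, numeric(1))
      if (max(drop_p) > p_remove) {
        selected <- setdiff(selected, selected[which.max(drop_p)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0) {
    return(list(selected = character(), score = rep(0, nrow(data)), fit = NULL))
  }
  fit <- fit_cox(data, time, event, selected)
  list(selected = selected, score = fit$linear_predictor, fit = fit)
}

#' @export
print.bioage_cox <- function(x, ...) {
  cat(sprintf("Cox fit: %d covariates, %d events / %d subjects, ll = %.3f (null %.3f)\n",
              length(x$coefficients), x$n_events, x$n, x$ll, x$ll_null))
  invisible(x)
}
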