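#' Configure the end-to-end biomarker-age pipeline
#'
#' @param cohort A cohort data frame, or `NULL` to simulate one.
#' @param sim A [sim_config()] used when `cohort` is `NULL`.
#' @param seed Integer seed recorded in the report and used for simulation.
#' @param biomarkers Biomarker column names; defaults to columns matching
#'   `^bm` for simulated cohorts.
#' @param sexes Sex strata to run (`"M"`, `"F"`); every model is sex-specific.
#' @param outcomes Named list; each element has `time`, `event`, and
#'   `risk_set` (`"all"` or `"no_prior_admission"`).
#' @param covariates Adjustment covariates for the C-index analyses.
#' @param population `"healthy"` fits and evaluates on the healthy subset;
#'   `"whole"` fits on the healthy subset but scores and evaluates everyone.
#' @param rules Healthy-filter rule set ([healthy_filter_rules()]).
#' @param eigen_threshold Component retention threshold (eigenvalue scale).
#' @param loading_cutoff Primary-biomarker |loading| cutoff.
#' @param acceleration_threshold Years for younger/older groups.
#' @param bin_width Calibration bin width (years).
#' @param reduced_panel_size Components used by [reduced_panel_analysis()].
#' @param benchmark Run the stepwise-Cox benchmark mortality score.
#' @return A list of class `bioage_pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, sim = sim_config(), seed = NULL,
                            biomarkers = NULL, sexes = c("M", "F"),
                            outcomes = list(
                              mortality = list(time = "mortality_time",
                                               event = "mortality_event",
                                               risk_set = "all"),
                              admissions = list(time = "admissions_time",
                                                event = "admissions_event",
                                                risk_set = "no_prior_admission")
                            ),
                            covariates = c("imd_quintile", "smoking",
                                           "alcohol", "center"),
                            population = c("healthy", "whole"),
                            rules = healthy_filter_rules(),
                            eigen_threshold = 1 / 3, loading_cutoff = 0.5,
                            acceleration_threshold = 5, bin_width = 2.5,
                            reduced_panel_size = 10, benchmark = TRUE) {
  structure(
    list(cohort = cohort, sim = sim, seed = seed, biomarkers = biomarkers,
         sexes = sexes, outcomes = outcomes, covariates = covariates,
         population = match.arg(population), rules = rules,
         eigen_threshold = eigen_threshold, loading_cutoff = loading_cutoff,
         acceleration_threshold = acceleration_threshold,
         bin_width = bin_width, reduced_panel_size = reduced_panel_size,
         benchmark = benchmark),
    class = "bioage_pipeline_config"
  )
}

#' Run the full biomarker-age pipeline
#'
#' Orchestrates simulate/ingest -> healthy filter -> per-sex components ->
#' per-sex Klemera-Doubal biological age -> per-outcome survival evaluation,
#' with calibration, importance, age-acceleration Kaplan-Meier analyses and
#' (optionally) the stepwise-Cox benchmark mortality score. Component and
#' KDM models are always fit on the healthy subset of each sex; in
#' `population = "whole"` mode they are then applied to every row of that
#' sex and the evaluation is rerun without the filter.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `bioage_report`: `audit` (filter counts),
#'   per-sex `strata` (each with `components`, `kdm`, `importance`,
#'   `calibration`, `linearity`, `acceleration_fractions`, `evaluations`
#'   per outcome, `benchmark`, and the scored cohort `data` with a `ba`
#'   column), plus the echoed config and seed.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(
#'   sim = sim_config(n_participants = 1500, seed = 7), seed = 7))
#' summary_table(rep)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bioage_pipeline_config"))
  cohort <- config$cohort
  if (is.null(cohort)) {
    sim <- config$sim
    if (!is.null(config$seed)) sim$seed <- config$seed
    cohort <- generate_cohort(sim)
  }
  cohort <- tibble::as_tibble(cohort)
  biomarkers <- config$biomarkers %||% grep("^bm", names(cohort), value = TRUE)
  if (length(biomarkers) == 0) abort("no biomarker columns found or configured")

  filt <- apply_healthy_filter(cohort, config$rules)
  healthy_ids <- filt$cohort$id

  strata <- purrr::map(setNames(config$sexes, config$sexes), function(sx) {
    run_stratum(cohort, healthy_ids, sx, biomarkers, config)
  })

  structure(
    list(audit = filt$audit, n_total = nrow(cohort),
         n_healthy = nrow(filt$cohort), strata = strata,
         config = config, seed = config$seed),
    class = "bioage_report"
  )
}

run_stratum <- function(cohort, healthy_ids, sx, biomarkers, config) {
  rows_sex <- cohort[cohort$sex == sx, , drop = FALSE]
  is_healthy <- rows_sex$id %in% healthy_ids
  if (sum(is_healthy) < length(biomarkers) + 2) {
    abort(sprintf("stratum %s: healthy fit subset too small (%d rows)",
                  sx, sum(is_healthy)))
  }
  scored <- if (config$population == "healthy") {
    rows_sex[is_healthy, , drop = FALSE]
  } else {
    rows_sex
  }
  fit_rows <- if (config$population == "healthy") NULL else which(is_healthy)

  cm <- fit_components(scored, biomarkers, fit_rows = fit_rows,
                       threshold = config$eigen_threshold,
                       cutoff = config$loading_cutoff)
  fit_idx <- fit_rows %||% seq_len(nrow(scored))
  km_model <- fit_kdm(cm$scores[fit_idx, , drop = FALSE], scored$ca[fit_idx],
                      sex = sx)
  scored$ba <- compute_ba(cm$scores, km_model)

  importance <- component_importance(km_model)
  calib <- calibration_table(scored$ba, scored$ca,
                             bin_width = config$bin_width,
                             origin = floor(min(scored$ca)))
  acc <- age_acceleration_groups(scored$ba, scored$ca,
                                 config$acceleration_threshold)
  linearity <- age_trend_summary(scored[fit_idx, , drop = FALSE], biomarkers)

  evaluations <- purrr::map(config$outcomes, function(oc) {
    dat <- scored
    if (identical(oc$risk_set, "no_prior_admission")) dat <- admission_risk_set(dat)
    evaluate_outcome(dat, ba_col = "ba", ca_col = "ca",
                     time = oc$time, event = oc$event,
                     covariates = config$covariates,
                     acceleration_threshold = config$acceleration_threshold)
  })

  benchmark <- NULL
  if (isTRUE(config$benchmark) && all(c("mortality", "admissions") %in%
                                      names(config$outcomes))) {
    benchmark <- benchmark_mortality_score(scored, cm, config)
  }

  list(sex = sx, n = nrow(scored), components = cm, kdm = km_model,
       importance = importance, calibration = calib,
       acceleration_fractions = acc$fractions, linearity = linearity,
       evaluations = evaluations, benchmark = benchmark, data = scored)
}

benchmark_mortality_score <- function(scored, cm, config) {
  mo <- config$outcomes$mortality
  ad <- config$outcomes$admissions
  dat <- dplyr::bind_cols(scored, cm$scores)
  sw <- stepwise_mortality_score(dat, names(cm$scores), mo$time, mo$event)
  dat$.mortality_score_ <- sw$score
  adm <- dat
  if (identical(ad$risk_set, "no_prior_admission")) adm <- admission_risk_set(adm)
  c_score <- harrells_c(adm$.mortality_score_, adm[[ad$time]], adm[[ad$event]])
  c_ba <- harrells_c(adm$ba, adm[[ad$time]], adm[[ad$event]])
  list(
    selected = sw$selected,
    c_admissions = dplyr::bind_rows(
      dplyr::mutate(c_score, predictor = "mortality_score"),
      dplyr::mutate(c_ba, predictor = "ba")
    ) |> dplyr::relocate("predictor"),
    improvement_ba = c_ba$c_index - c_score$c_index
  )
}

#' Per-biomarker age-trend diagnostics
#'
#' Linear slope of each biomarker on chronological age plus the
#' t-statistic of a quadratic term, flagging curvature (a stand-in for the
#' visual linearity assessment done on real panels).
#'
#' @param data Data frame with `ca` and the biomarker columns.
#' @param biomarkers Character vector of biomarker columns.
#' @param ca_col Chronological-age column name.
#' @return Tibble `biomarker`, `slope`, `quadratic_t`, `curved`
#'   (|t| > 4, a conservative flag at cohort sample sizes).
#' @export
age_trend_summary <- function(data, biomarkers, ca_col = "ca") {
  ca <- data[[ca_col]]
  ca2 <- ca^2
  purrr::map_dfr(biomarkers, function(bm) {
    f1 <- stats::lm(data[[bm]] ~ ca)
    f2 <- stats::lm(data[[bm]] ~ ca + ca2)
    qt <- summary(f2)$coefficients
    qt <- if (nrow(qt) >= 3) qt["ca2", "t value"] else NA_real_
    tibble::tibble(biomarker = bm, slope = unname(coef(f1)[2]),
                   quadratic_t = qt, curved = is.finite(qt) && abs(qt) > 4)
  })
}

#' Reduced-panel sensitivity analysis
#'
#' Repeats the components -> KDM -> evaluation pipeline using only the
#' primary biomarkers (|rotated loading| > `cutoff`) of the `top_k` most
#' important components of a fitted stratum, mirroring the question of
#' whether a smaller, more practical panel retains the explanatory power of
#' the full one. A component with no loading above the cutoff contributes
#' its single strongest-loading biomarker.
#'
#' @param stratum One element of a [run_pipeline()] report's `strata`.
#' @param config The [pipeline_config()] used for the main run.
#' @param top_k Number of top-importance components whose biomarkers are
#'   kept.
#' @param cutoff |loading| threshold for a primary biomarker.
#' @return A list with `biomarkers` (the reduced panel), `kdm`, `ba`
#'   (reduced-panel biological ages), `evaluations`, and `comparison`
#'   (tibble of proportions explained, full versus reduced panel).
#' @export
reduced_panel_analysis <- function(stratum, config, top_k = NULL, cutoff = 0.5) {
  top_k <- top_k %||% config$reduced_panel_size
  cm <- stratum$components
  n_ret <- length(cm$retained)
  if (top_k < 1) abort("`top_k` must be at least 1")
  if (top_k > n_ret) {
    abort(sprintf("`top_k` (%d) exceeds the %d retained components", top_k, n_ret))
  }
  top_components <- stratum$importance$component[seq_len(top_k)]
  chr <- cm$characterization
  panel <- unique(unlist(purrr::map(top_components, function(cp) {
    row <- chr[chr$component == cp, ]
    pl <- row$primary[[1]]
    # refresh the primary list under a non-default cutoff
    ld <- cm$rotated_loadings[, cp]
    pl <- rownames(cm$rotated_loadings)[abs(ld) > cutoff]
    if (length(pl) == 0) pl <- row$label
    pl
  })))

  dat <- stratum$data
  cm_red <- fit_components(dat, panel, threshold = config$eigen_threshold,
                           cutoff = config$loading_cutoff)
  km_red <- fit_kdm(cm_red$scores, dat$ca, sex = stratum$sex)
  dat$ba <- compute_ba(cm_red$scores, km_red)

  evaluations <- purrr::map(config$outcomes, function(oc) {
    d <- dat
    if (identical(oc$risk_set, "no_prior_admission")) d <- admission_risk_set(d)
    evaluate_outcome(d, "ba", "ca", time = oc$time, event = oc$event,
                     covariates = config$covariates,
                     acceleration_threshold = config$acceleration_threshold)
  })

  comparison <- tibble::tibble(
    outcome = names(config$outcomes),
    prop_full = purrr::map_dbl(stratum$evaluations, "proportion_explained"),
    prop_reduced = purrr::map_dbl(evaluations, "proportion_explained")
  )
  list(biomarkers = panel, components = cm_red, kdm = km_red, ba = dat$ba,
       evaluations = evaluations, comparison = comparison)
}

#' One-table summary of a pipeline report
#'
#' @param report A [run_pipeline()] result.
#' @return Tibble with one row per sex x outcome: KDM R-squared,
#'   SD(BA - CA), proportion explained, LRT p-value, and C-indices.
#' @export
summary_table <- function(report) {
  stopifnot(inherits(report, "bioage_report"))
  purrr::map_dfr(report$strata, function(st) {
    purrr::imap_dfr(st$evaluations, function(ev, oc) {
      ci <- function(pred, adj) {
        v <- ev$c_indices
        v$c_index[v$predictor == pred & v$adjusted == adj][1]
      }
      tibble::tibble(
        sex = st$sex, outcome = oc, n = ev$n, n_events = ev$n_events,
        kdm_r_squared = st$kdm$r_squared, sd_ba_minus_ca = st$kdm$ba_sd_diff,
        proportion_explained = ev$proportion_explained,
        lrt_p = ev$lrt$p_value,
        c_ca = ci("ca", FALSE), c_ba = ci("ba", FALSE),
        c_ba_ca = ci("ba_ca", FALSE),
        log_rank_p = ev$log_rank$p_value
      )
    })
  })
}

#' @export
print.bioage_report <- function(x, ...) {
  cat(sprintf("bioage pipeline report: %d participants, %d healthy (%.1f%%)\n",
              x$n_total, x$n_healthy, 100 * x$n_healthy / x$n_total))
  print(summary_table(x))
  invisible(x)
}
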