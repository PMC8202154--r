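#' Configure a synthetic biomarker-aging cohort
#'
#' Builds the configuration for [generate_cohort()]. The generator emulates
#' the statistical structure a biomarker-age analysis assumes: chronological
#' age (CA) uniform on `age_range`; a latent biological-age offset
#' `delta ~ N(0, sigma_delta^2)` so that the true biological age is
#' `ba_true = ca + delta`; biomarkers linear in `ba_true` with block-correlated
#' residuals (adiposity, lung-function, blood-pressure and lipid panels move
#' together); two right-censored outcomes (chronic-disease mortality and
#' age-related hospital admission) whose hazards are log-linear in `ba_true`;
#' and healthy-filter eligibility fields whose failure probabilities increase
#' with `delta` (biologically older participants are likelier to be excluded).
#'
#' @param n_participants Number of rows to simulate.
#' @param sex_ratio Fraction of women in the cohort, in \[0, 1\].
#' @param age_range Length-2 numeric, years; CA is drawn uniformly on it.
#' @param sigma_delta SD (years) of the latent biological-age offset.
#' @param biomarkers_per_block Integer vector, biomarkers in each correlated
#'   block. Its length is the number of blocks.
#' @param slopes Biomarker-age slopes `k_j` (units/year); either one numeric
#'   vector used for both sexes or a list with elements `M` and `F`. Use 0 for
#'   a flat (non-informative) biomarker.
#' @param intercepts Biomarker intercepts `q_j` (units).
#' @param residual_sds Residual SDs `s_j` (units), all > 0.
#' @param block_correlation Within-block residual correlation, in \[0, 1).
#' @param hazard_log_hr_per_year Named numeric (`mortality`, `admissions`):
#'   log hazard ratio per year of `ba_true` for each outcome.
#' @param baseline_hazards Named numeric (`mortality`, `admissions`): baseline
#'   event rates (1/year) at the cohort-mean `ba_true`.
#' @param followup_range Length-2 numeric, years; administrative censoring is
#'   uniform on it (stands in for staggered recruitment with a fixed end date).
#' @param eligibility_params List with `base_fail` (per-rule failure
#'   probability at `delta = 0`), `delta_slope` (log-odds increase in failure
#'   per year of `delta`), and `prior_admission_base` (baseline probability of
#'   a pre-baseline age-related admission).
#' @param biomarker_names Optional character vector of biomarker column names.
#' @param seed Integer seed; with a fixed seed the generated table is
#'   byte-identical across runs.
#'
#' @return A list of class `bioage_sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_participants = 10000,
                       sex_ratio = 0.54,
                       age_range = c(40, 70),
                       sigma_delta = 5,
                       biomarkers_per_block = c(3, 3, 3, 3),
                       slopes = NULL,
                       intercepts = NULL,
                       residual_sds = NULL,
                       block_correlation = 0.3,
                       hazard_log_hr_per_year = c(mortality = 0.09, admissions = 0.05),
                       baseline_hazards = c(mortality = 0.002, admissions = 0.022),
                       followup_range = c(6, 12),
                       eligibility_params = list(),
                       biomarker_names = NULL,
                       seed = NULL) {
  p <- sum(biomarkers_per_block)
  if (is.null(slopes)) {
    slopes <- default_slopes(biomarkers_per_block)
  }
  if (is.null(intercepts)) intercepts <- rep(0, p)
  if (is.null(residual_sds)) residual_sds <- rep(1, p)
  if (is.null(biomarker_names)) {
    biomarker_names <- sprintf("bm%02d", seq_len(p))
  }
  ep <- utils::modifyList(
    list(base_fail = 0.18, delta_slope = 0.06, prior_admission_base = 0.08),
    eligibility_params
  )

  cfg <- structure(
    list(
      n_participants = n_participants, sex_ratio = sex_ratio,
      age_range = age_range, sigma_delta = sigma_delta,
      biomarkers_per_block = biomarkers_per_block,
      slopes = slopes, intercepts = intercepts, residual_sds = residual_sds,
      block_correlation = block_correlation,
      hazard_log_hr_per_year = hazard_log_hr_per_year,
      baseline_hazards = baseline_hazards,
      followup_range = followup_range,
      eligibility_params = ep,
      biomarker_names = biomarker_names,
      seed = seed
    ),
    class = "bioage_sim_config"
  )
  validate_sim_config(cfg)
}

default_slopes <- function(biomarkers_per_block) {
  # varied trend strengths per block (adiposity weak; lung strongest and
  # declining; blood pressure rising; lipids moderate), calibrated so the
  # healthy-subset KDM explains roughly half the variance in CA
  block_scale <- rep_len(c(0.034, -0.102, 0.085, 0.051),
                         length(biomarkers_per_block))
  unlist(purrr::map2(
    block_scale, biomarkers_per_block,
    function(sc, m) sc * seq(1, 0.7, length.out = m)
  ), use.names = FALSE)
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("invalid simulation config: `%s` %s", field, msg),
          class = "bioage_config_error")
  }
  p <- sum(cfg$biomarkers_per_block)
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1) {
    bad("n_participants", "must be a positive count")
  }
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) bad("sex_ratio", "must lie in [0, 1]")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2]) {
    bad("age_range", "must be an increasing length-2 range")
  }
  if (cfg$sigma_delta < 0) bad("sigma_delta", "must be >= 0")
  for (sx in c("M", "F")) {
    k <- slopes_for_sex(cfg, sx)
    if (length(k) != p) bad("slopes", sprintf("needs one entry per biomarker (%d)", p))
  }
  if (length(cfg$intercepts) != p) bad("intercepts", sprintf("needs %d entries", p))
  if (length(cfg$residual_sds) != p) bad("residual_sds", sprintf("needs %d entries", p))
  # s_j = 0 is permitted as a degenerate noise-free limit used in testing
  if (any(cfg$residual_sds < 0)) bad("residual_sds", "must all be >= 0")
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1) {
    bad("block_correlation", "must lie in [0, 1)")
  }
  if (any(cfg$baseline_hazards < 0)) bad("baseline_hazards", "must be >= 0")
  if (length(cfg$followup_range) != 2 || any(cfg$followup_range < 0) ||
      cfg$followup_range[1] > cfg$followup_range[2]) {
    bad("followup_range", "must be a non-negative, non-decreasing range")
  }
  ep <- cfg$eligibility_params
  if (any(ep$base_fail < 0) || any(ep$base_fail > 1)) {
    bad("eligibility_params$base_fail", "probabilities must lie in [0, 1]")
  }
  if (ep$prior_admission_base < 0 || ep$prior_admission_base > 1) {
    bad("eligibility_params$prior_admission_base", "must lie in [0, 1]")
  }
  cfg
}

slopes_for_sex <- function(cfg, sex) {
  if (is.list(cfg$slopes)) cfg$slopes[[sex]] else cfg$slopes
}

#' Block loading for a target within-block correlation
#'
#' In the biomarker factor model `x = q + k * ba_true + b * eta + eps`, two
#' biomarkers in the same block with common residual SD `s` have residual
#' correlation `b^2 / (b^2 + s^2)`. This returns the `b` achieving a target.
#'
#' @param rho Target within-block residual correlation in \[0, 1).
#' @param s Residual SD of the biomarkers.
#' @return The block-factor loading `b`.
#' @export
block_loading_for_correlation <- function(rho, s = 1) {
  stopifnot(rho >= 0, rho < 1, s >= 0)
  s * sqrt(rho / (1 - rho))
}

#' Generate a synthetic cohort
#'
#' Draws a complete per-participant table: demographics, latent `ba_true`,
#' biomarkers, eligibility fields and covariates, and two right-censored
#' outcomes. With `config$seed` set, the output is reproducible.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per participant: `id`, `sex` (`"M"`/`"F"`),
#'   `ca`, `delta`, `ba_true`, one column per biomarker, eligibility fields
#'   (`medication`, `self_rated_health`, `walk_pace`, `smoking`,
#'   `prior_episodes`, `prior_disease`, `prior_admission`), covariates
#'   (`imd_quintile`, `alcohol`, `center`), and per outcome
#'   `<outcome>_event` / `<outcome>_time`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 200, seed = 1))
#' dplyr::glimpse(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "bioage_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants

  sex <- ifelse(runif(n) < config$sex_ratio, "F", "M")
  ca <- runif(n, config$age_range[1], config$age_range[2])
  delta <- rnorm(n, 0, config$sigma_delta)
  ba_true <- ca + delta

  base <- tibble::tibble(
    id = sprintf("P%06d", seq_len(n)),
    sex = sex, ca = ca, delta = delta, ba_true = ba_true
  )

  bm_mat <- matrix(NA_real_, n, length(config$biomarker_names),
                   dimnames = list(NULL, config$biomarker_names))
  for (sx in c("M", "F")) {
    idx <- sex == sx
    if (any(idx)) {
      bm_mat[idx, ] <- as.matrix(generate_biomarkers(ba_true[idx], config, sex = sx))
    }
  }
  bm <- tibble::as_tibble(bm_mat)

  elig <- generate_eligibility(delta, config)
  outc <- generate_outcomes(ba_true, config)

  dplyr::bind_cols(base, bm, elig, outc)
}

#' Generate biomarker columns from true biological age
#'
#' Implements the biomarker factor model `x_j = q_j + k_j * ba_true +
#' b_g * eta_g + eps_j`, where `eta_g ~ N(0, 1)` is shared within block `g`
#' (giving correlated adiposity / lung / blood-pressure / lipid panels) and
#' `eps_j ~ N(0, s_j^2)`. Flat biomarkers use `k_j = 0`.
#'
#' @param ba_true Numeric vector of true biological ages (CA + latent offset).
#' @param config A [sim_config()].
#' @param sex `"M"` or `"F"`; selects the sex-specific slope panel.
#' @return A tibble of biomarker columns, one row per element of `ba_true`.
#' @export
generate_biomarkers <- function(ba_true, config, sex = "M") {
  k <- slopes_for_sex(config, sex)
  q <- config$intercepts
  s <- config$residual_sds
  p <- length(k)
  n <- length(ba_true)

  block <- rep(seq_along(config$biomarkers_per_block), config$biomarkers_per_block)
  rho <- config$block_correlation
  eta <- matrix(rnorm(n * length(config$biomarkers_per_block)), n)

  x <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    b_g <- block_loading_for_correlation(rho, s[j])
    x[, j] <- q[j] + k[j] * ba_true + b_g * eta[, block[j]] +
      if (s[j] > 0) rnorm(n, 0, s[j]) else 0
  }
  colnames(x) <- config$biomarker_names
  tibble::as_tibble(x)
}

#' Generate right-censored outcomes from true biological age
#'
#' Event times are exponential with hazard
#' `lambda0 * exp(beta * (ba_true - mean(ba_true)))`; censoring times are
#' uniform on `followup_range`, independent of everything else. The observed
#' time is the minimum, the event indicator marks which came first. The two
#' outcomes are generated independently given `ba_true`.
#'
#' @inheritParams generate_biomarkers
#' @return A tibble with columns `<outcome>_event` (0/1) and `<outcome>_time`
#'   (years, > 0) for each configured outcome.
#' @export
generate_outcomes <- function(ba_true, config) {
  n <- length(ba_true)
  centred <- ba_true - mean(ba_true)
  out <- purrr::imap(config$baseline_hazards, function(lambda0, nm) {
    beta <- config$hazard_log_hr_per_year[[nm]]
    cens <- runif(n, config$followup_range[1], config$followup_range[2])
    haz <- lambda0 * exp(beta * centred)
    evt_time <- ifelse(haz > 0, rexp(n) / haz, Inf)
    tibble::tibble(
      event = as.integer(evt_time <= cens),
      time = pmin(evt_time, cens)
    ) |> setNames(paste0(nm, c("_event", "_time")))
  })
  dplyr::bind_cols(out)
}

#' Generate eligibility fields and covariates
#'
#' Healthy-filter fields fail with probability
#' `plogis(qlogis(base_fail) + delta_slope * delta)`, so biologically older
#' participants (larger latent offset `delta`) are likelier to fail each rule:
#' chronic-disease medication, poor self-rated health, slow walking pace,
#' current smoking, >2 prior secondary-care episodes, prior age-related
#' disease. A separate `prior_admission` flag drives the admissions risk set.
#' Covariates (deprivation quintile, alcohol frequency, assessment center)
#' are drawn from fixed categorical distributions.
#'
#' @param delta Numeric vector of latent biological-age offsets (years).
#' @param config A [sim_config()].
#' @return A tibble of eligibility fields and covariates.
#' @export
generate_eligibility <- function(delta, config) {
  ep <- config$eligibility_params
  n <- length(delta)
  rules <- c("medication", "self_rated_health", "walk_pace", "smoking",
             "prior_episodes", "prior_disease")
  base_fail <- rep_len(ep$base_fail, length(rules))
  names(base_fail) <- rules

  fail_p <- function(p0) {
    if (p0 <= 0) rep(0, n)
    else if (p0 >= 1) rep(1, n)
    else plogis(qlogis(p0) + ep$delta_slope * delta)
  }
  fails <- purrr::map(base_fail, function(p0) runif(n) < fail_p(p0))

  pa0 <- ep$prior_admission_base
  prior_adm <- if (pa0 <= 0) rep(0L, n) else if (pa0 >= 1) rep(1L, n) else {
    as.integer(runif(n) < plogis(qlogis(pa0) + ep$delta_slope * delta))
  }

  tibble::tibble(
    medication = as.integer(fails$medication),
    self_rated_health = ifelse(
      fails$self_rated_health,
      sample(c("fair", "poor"), n, TRUE, c(0.7, 0.3)),
      sample(c("excellent", "good"), n, TRUE, c(0.3, 0.7))
    ),
    walk_pace = ifelse(
      fails$walk_pace, "slow",
      sample(c("steady", "brisk"), n, TRUE, c(0.5, 0.5))
    ),
    smoking = ifelse(
      fails$smoking, "current",
      sample(c("never", "previous"), n, TRUE, c(0.65, 0.35))
    ),
    prior_episodes = ifelse(fails$prior_episodes, 3L + rpois(n, 1),
                            sample(0:2, n, TRUE, c(0.5, 0.3, 0.2))),
    prior_disease = as.integer(fails$prior_disease),
    prior_admission = prior_adm,
    imd_quintile = sample(1:5, n, TRUE),
    alcohol = sample(
      c("never", "special", "monthly", "weekly", "often", "daily"),
      n, TRUE, c(0.08, 0.11, 0.11, 0.26, 0.23, 0.21)
    ),
    center = sprintf("C%02d", sample(1:22, n, TRUE))
  )
}
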