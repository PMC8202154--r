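#' Healthy-subpopulation filter rules
#'
#' The default baseline-health filter: no chronic-disease medication, good or
#' excellent self-rated health, steady/brisk walking pace, never/ex-smoker,
#' at most `max_prior_episodes` prior secondary-care episodes, and no prior
#' chronic age-related disease. Rules are configuration, not code: each is a
#' named one-sided formula evaluated against the cohort columns, applied in
#' the listed order.
#'
#' @param max_prior_episodes Maximum prior secondary-care episodes allowed.
#' @return A named list of one-sided formulas (class `bioage_filter_rules`).
#' @export
healthy_filter_rules <- function(max_prior_episodes = 2) {
  structure(
    list(
      medication = ~ medication == 0,
      self_rated_health = ~ self_rated_health %in% c("excellent", "good"),
      walk_pace = ~ walk_pace %in% c("steady", "brisk"),
      smoking = ~ smoking %in% c("never", "previous"),
      prior_episodes = stats::as.formula(
        sprintf("~ prior_episodes <= %d", max_prior_episodes)
      ),
      prior_disease = ~ prior_disease == 0
    ),
    class = "bioage_filter_rules"
  )
}

#' Apply the healthy-subpopulation filter
#'
#' Keeps rows that satisfy every rule; excluded rows are attributed to the
#' first rule (in order) that they fail, giving an order-dependent audit
#' trail. The filter is idempotent and the audit counts sum to
#' `nrow(cohort) - nrow(subcohort)`.
#'
#' @param cohort A cohort data frame.
#' @param rules A named list of one-sided formulas over cohort columns, e.g.
#'   [healthy_filter_rules()]. An empty list returns the cohort unchanged.
#' @return A list with `cohort` (the passing subcohort, as a tibble) and
#'   `audit` (tibble with `rule`, `n_excluded`, in rule order).
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 500, seed = 1))
#' res <- apply_healthy_filter(cohort, healthy_filter_rules())
#' res$audit
#' @export
apply_healthy_filter <- function(cohort, rules = healthy_filter_rules()) {
  cohort <- tibble::as_tibble(cohort)
  for (rl in rules) {
    missing <- setdiff(all.vars(rl), names(cohort))
    if (length(missing)) {
      abort(sprintf("filter rule references missing column(s): %s",
                    paste(missing, collapse = ", ")),
            class = "bioage_schema_error")
    }
  }
  n <- nrow(cohort)
  first_fail <- rep(NA_integer_, n)
  for (i in rev(seq_along(rules))) {
    ok <- rlang::eval_tidy(rules[[i]][[2]], data = cohort)
    if (!is.logical(ok) || length(ok) != n) {
      abort(sprintf("rule `%s` did not evaluate to one logical per row",
                    names(rules)[i]), class = "bioage_schema_error")
    }
    first_fail[!ok] <- i
  }
  audit <- tibble::tibble(
    rule = names(rules) %||% character(),
    n_excluded = tabulate(first_fail, nbins = length(rules))
  )
  list(
    cohort = cohort[is.na(first_fail), , drop = FALSE],
    audit = audit
  )
}

#' Risk set for the admissions outcome
#'
#' Removes participants admitted to hospital with an age-related diagnosis
#' before baseline; they are not at risk of an incident admission. Mortality
#' analyses use the unrestricted cohort.
#'
#' @param cohort A cohort data frame with a `prior_admission` 0/1 column.
#' @return The subset with `prior_admission == 0`, as a tibble.
#' @export
admission_risk_set <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  if (!"prior_admission" %in% names(cohort)) {
    abort("column `prior_admission` is required for the admissions risk set",
          class = "bioage_schema_error")
  }
  dplyr::filter(cohort, .data$prior_admission == 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
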