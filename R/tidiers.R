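#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a component model
#'
#' @param x A `bioage_components` object.
#' @param ... Unused.
#' @return One row per biomarker x retained component with the rotated
#'   loading.
#' @export
tidy.bioage_components <- function(x, ...) {
  L <- x$rotated_loadings
  tibble::tibble(
    biomarker = rep(rownames(L), ncol(L)),
    component = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L)
  )
}

#' @rdname tidy.bioage_components
#' @export
glance.bioage_components <- function(x, ...) {
  tibble::tibble(
    n_biomarkers = length(x$biomarkers),
    n_components = length(x$eigenvalues),
    n_retained = length(x$retained),
    threshold = x$threshold,
    variance_retained = sum(x$eigenvalues[x$retained]) / sum(x$eigenvalues)
  )
}

#' Tidy a Klemera-Doubal model
#'
#' @param x A `bioage_kdm` object.
#' @param ... Unused.
#' @return One row per component: intercept `q`, slope `k`, residual RMSE
#'   `s`, KDM weight `w`, and whether the component is informative.
#' @export
tidy.bioage_kdm <- function(x, ...) {
  x$regressions[, c("component", "q", "k", "s", "w", "informative")]
}

#' @rdname tidy.bioage_kdm
#' @export
glance.bioage_kdm <- function(x, ...) {
  tibble::tibble(
    sex = x$sex,
    n_components = nrow(x$regressions),
    n_informative = sum(x$regressions$informative),
    r_squared = x$r_squared,
    sd_ba_minus_ca = x$ba_sd_diff,
    ca_correction = isTRUE(x$ca_correction)
  )
}

#' Tidy a Cox fit
#'
#' @param x A `bioage_cox` object.
#' @param ... Unused.
#' @return One row per coefficient.
#' @export
tidy.bioage_cox <- function(x, ...) {
  if (length(x$coefficients) == 0) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.bioage_cox
#' @export
glance.bioage_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    loglik = x$ll, loglik_null = x$ll_null,
    converged = x$converged
  )
}

#' Tidy an evaluation report
#'
#' @param x A `bioage_eval` object.
#' @param ... Unused.
#' @return The C-index table (one row per predictor x adjustment).
#' @export
tidy.bioage_eval <- function(x, ...) {
  x$c_indices
}

#' @rdname tidy.bioage_eval
#' @export
glance.bioage_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    proportion_explained = x$proportion_explained,
    lrt_statistic = x$lrt$statistic, lrt_p = x$lrt$p_value,
    log_rank_p = x$log_rank$p_value
  )
}
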