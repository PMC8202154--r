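#' Standardize biomarkers using fit-subset statistics
#'
#' Computes z-scores `(x - mean) / sd` with means and SDs estimated on
#' `fit_rows` only (typically the healthy subset of one sex), so the same
#' parameters can transform held-out or whole-population rows.
#'
#' @param data A data frame containing the biomarker columns.
#' @param biomarkers Character vector of biomarker column names.
#' @param fit_rows Logical or integer row index into `data` defining the
#'   subset whose means/SDs are used; defaults to all rows.
#' @return A list with `z` (tibble of z-scores for all rows of `data`) and
#'   `params` (tibble: `biomarker`, `mean`, `sd`).
#' @export
standardize_biomarkers <- function(data, biomarkers, fit_rows = NULL) {
  x <- as.matrix(data[, biomarkers, drop = FALSE])
  if (anyNA(x)) abort("biomarker columns contain missing values",
                      class = "bioage_schema_error")
  fit <- if (is.null(fit_rows)) x else x[fit_rows, , drop = FALSE]
  mu <- colMeans(fit)
  sg <- apply(fit, 2, sd)
  if (any(sg == 0)) {
    abort(sprintf("degenerate (zero-variance) biomarker column(s): %s",
                  paste(biomarkers[sg == 0], collapse = ", ")),
          class = "bioage_degenerate_error")
  }
  z <- sweep(sweep(x, 2, mu), 2, sg, "/")
  list(
    z = tibble::as_tibble(z),
    params = tibble::tibble(biomarker = biomarkers, mean = unname(mu), sd = unname(sg))
  )
}

apply_standardization <- function(data, params) {
  x <- as.matrix(data[, params$biomarker, drop = FALSE])
  z <- sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
  tibble::as_tibble(z)
}

#' Principal components of standardized biomarkers
#'
#' Eigen-decomposition of the sample correlation matrix of the fit rows.
#' Loadings are scaled eigenvectors (`loading_ij = v_ij * sqrt(lambda_j)`),
#' so eigenvalues sum to the number of biomarkers and squared loadings of a
#' component sum to its eigenvalue. Scores are unit-variance in the fit
#' sample (`z v_j / sqrt(lambda_j)`).
#'
#' @param z Matrix or data frame of z-scored biomarkers (fit rows).
#' @return A list with `eigenvalues` (descending), `loadings`
#'   (biomarkers x components matrix), and `scores` (unit-variance, same
#'   rows as `z`).
#' @export
fit_pca <- function(z) {
  z <- as.matrix(z)
  if (anyNA(z)) abort("missing values are not allowed in PCA input",
                      class = "bioage_schema_error")
  if (nrow(z) < ncol(z)) abort("PCA requires at least as many rows as biomarkers")
  R <- stats::cor(z)
  eg <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  V <- eg$vectors
  loadings <- sweep(V, 2, sqrt(lambda), "*")
  # unit-variance scores; zero eigenvalues give all-zero scores
  inv <- ifelse(lambda > .Machine$double.eps^0.5, 1 / sqrt(lambda), 0)
  zc <- scale(z, center = TRUE, scale = apply(z, 2, sd))
  scores <- zc %*% sweep(V, 2, inv, "*")
  cn <- paste0("PC", seq_along(lambda))
  dimnames(loadings) <- list(colnames(z), cn)
  colnames(scores) <- cn
  list(eigenvalues = lambda, loadings = loadings, scores = scores)
}

#' Retain components by the eigenvalue rule
#'
#' Keeps components whose eigenvalue exceeds `threshold` on the
#' average-variance scale: for correlation-matrix PCA the average eigenvalue
#' is 1, so the default keeps components explaining more than a third of the
#' variation an average biomarker carries.
#'
#' @param eigenvalues Numeric vector of eigenvalues in descending order.
#' @param threshold Retention threshold; strictly greater-than is applied.
#' @return Integer indices of retained components, in descending-eigenvalue
#'   order.
#' @export
retain_components <- function(eigenvalues, threshold = 1 / 3) {
  which(eigenvalues > threshold)
}

#' Varimax criterion of a loading matrix
#'
#' Sum over components of the variance of the squared loadings; the quantity
#' the (raw) varimax rotation maximizes.
#'
#' @param loadings Numeric matrix (biomarkers x components).
#' @return The scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  sq <- loadings^2
  sum(apply(sq, 2, function(col) mean((col - mean(col))^2)))
}

#' Varimax rotation of retained loadings
#'
#' Orthogonally rotates the loading matrix towards simple structure
#' (each biomarker loading strongly on few components). Row communalities
#' are invariant. The rotation is made deterministic by a sign convention:
#' each rotated component is flipped so its largest-|loading| biomarker
#' loads positively.
#'
#' @param loadings Loadings of the retained components (biomarkers x m,
#'   m >= 2).
#' @param normalize Kaiser row-normalization during rotation; off by default
#'   (raw varimax).
#' @param eps Convergence tolerance on the rotation criterion.
#' @return A list with `loadings` (rotated), `rotation` (orthogonal m x m
#'   matrix, `loadings_in %*% rotation = loadings_out`), and `converged`.
#' @export
varimax_rotate <- function(loadings, normalize = FALSE, eps = 1e-8) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) < 2) abort("varimax rotation needs at least 2 components")
  vm <- stats::varimax(loadings, normalize = normalize, eps = eps)
  rot <- matrix(vm$rotmat, ncol(loadings))
  L <- loadings %*% rot
  # raw stats::varimax can stop short of the optimum on near-tied criteria;
  # a criterion decrease would break the ascent invariant, so fall back
  if (varimax_criterion(L) < varimax_criterion(loadings)) {
    warn("varimax rotation did not improve the criterion; returning input")
    rot <- diag(ncol(loadings))
    L <- loadings
  }
  flip <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  L <- sweep(L, 2, flip, "*")
  dimnames(L) <- dimnames(loadings)
  list(loadings = L, rotation = rot, converged = TRUE)
}

#' Characterize components by their strongest loadings
#'
#' For each component, lists the biomarkers whose |rotated loading| exceeds
#' `cutoff` (the component's "primary biomarkers"), ordered by |loading|,
#' and labels the component by its top biomarker. When nothing clears the
#' cutoff the label falls back to the largest-|loading| biomarker and the
#' primary list is empty.
#'
#' @param loadings Rotated loading matrix (biomarkers x components) with
#'   biomarker rownames.
#' @param cutoff Absolute-loading threshold for a "primary" biomarker.
#' @return A tibble with `component`, `label`, `primary` (list-column of
#'   character vectors), `n_primary`, and `top_loading`.
#' @export
characterize_components <- function(loadings, cutoff = 0.5) {
  loadings <- as.matrix(loadings)
  bm <- rownames(loadings) %||% sprintf("bm%02d", seq_len(nrow(loadings)))
  purrr::map_dfr(seq_len(ncol(loadings)), function(j) {
    a <- abs(loadings[, j])
    ord <- order(a, decreasing = TRUE)
    primary <- bm[ord][a[ord] > cutoff]
    n_primary <- length(primary)
    tibble::tibble(
      component = colnames(loadings)[j] %||% paste0("PC", j),
      label = bm[ord[1]],
      primary = list(primary),
      n_primary = n_primary,
      top_loading = unname(loadings[ord[1], j])
    )
  })
}

#' Fit the sex-specific component model
#'
#' End-to-end component stage: standardize the biomarkers on the fit rows,
#' run correlation-matrix PCA, retain components with eigenvalue > 1/3,
#' varimax-rotate the retained loadings, and score all rows of `data` on the
#' rotated components (unit fit-sample variance, pairwise uncorrelated).
#'
#' @param data Cohort data frame (any rows; scores are produced for all).
#' @param biomarkers Character vector of biomarker columns.
#' @param fit_rows Logical/integer index of rows used to fit (e.g. the
#'   healthy subset of one sex); defaults to all rows.
#' @param threshold Eigenvalue retention threshold (see
#'   [retain_components()]).
#' @param normalize Kaiser normalization for varimax (default off).
#' @param cutoff Primary-biomarker loading cutoff for
#'   [characterize_components()].
#' @return An object of class `bioage_components`: standardization params,
#'   eigenvalues, unrotated and rotated loadings, rotation matrix, retained
#'   index set, component characterization, and a `scores` tibble (all rows
#'   of `data`, columns = retained components).
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 400, seed = 2))
#' cm <- fit_components(cohort, biomarkers = grep("^bm", names(cohort), value = TRUE))
#' cm$eigenvalues
#' @export
fit_components <- function(data, biomarkers, fit_rows = NULL,
                           threshold = 1 / 3, normalize = FALSE, cutoff = 0.5) {
  std <- standardize_biomarkers(data, biomarkers, fit_rows)
  z_fit <- if (is.null(fit_rows)) std$z else std$z[fit_rows, , drop = FALSE]
  pca <- fit_pca(z_fit)
  retained <- retain_components(pca$eigenvalues, threshold)
  if (length(retained) == 0) abort("no components retained at this threshold")

  L_ret <- pca$loadings[, retained, drop = FALSE]
  if (length(retained) >= 2) {
    vr <- varimax_rotate(L_ret, normalize = normalize)
  } else {
    vr <- list(loadings = L_ret, rotation = diag(1), converged = TRUE)
  }

  # rotated unit-variance scores for ALL rows: z V_ret diag(1/sqrt(lambda)) R
  lambda_ret <- pca$eigenvalues[retained]
  V_ret <- sweep(pca$loadings[, retained, drop = FALSE], 2, sqrt(lambda_ret), "/")
  basis <- sweep(V_ret, 2, sqrt(lambda_ret), "/") %*% vr$rotation
  scores_all <- as.matrix(std$z) %*% basis
  colnames(scores_all) <- colnames(pca$loadings)[retained]
  colnames(vr$loadings) <- colnames(scores_all)

  structure(
    list(
      biomarkers = biomarkers,
      standardization = std$params,
      eigenvalues = pca$eigenvalues,
      loadings = pca$loadings,
      rotated_loadings = vr$loadings,
      rotation = vr$rotation,
      retained = retained,
      threshold = threshold,
      characterization = characterize_components(vr$loadings, cutoff),
      score_basis = basis,
      scores = tibble::as_tibble(scores_all)
    ),
    class = "bioage_components"
  )
}

#' Score new rows on a fitted component model
#'
#' @param object A `bioage_components` model.
#' @param newdata Data frame containing the model's biomarker columns.
#' @param ... Unused.
#' @return Tibble of rotated component scores for `newdata`.
#' @export
predict.bioage_components <- function(object, newdata, ...) {
  z <- apply_standardization(newdata, object$standardization)
  s <- as.matrix(z) %*% object$score_basis
  colnames(s) <- names(object$scores)
  tibble::as_tibble(s)
}

#' @export
print.bioage_components <- function(x, ...) {
  cat(sprintf(
    "Component model: %d biomarkers, %d/%d components retained (eigenvalue > %.3g)\n",
    length(x$biomarkers), length(x$retained), length(x$eigenvalues), x$threshold
  ))
  cat("Top components:\n")
  print(utils::head(x$characterization[, c("component", "label", "n_primary")], 10))
  invisible(x)
}
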