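test_that("age regressions match hand-computed OLS on a 5-point fixture", {
  ca <- c(40, 45, 50, 55, 60)
  score <- c(1.0, 1.8, 2.1, 3.2, 3.6)
  # independent oracle: textbook least-squares sums
  k_hat <- sum((ca - mean(ca)) * (score - mean(score))) / sum((ca - mean(ca))^2)
  q_hat <- mean(score) - k_hat * mean(ca)
  s_hat <- sqrt(sum((score - q_hat - k_hat * ca)^2) / (5 - 2))
  reg <- fit_age_regressions(cbind(PC1 = score), ca)
  expect_equal(reg$q, q_hat, tolerance = 1e-10)
  expect_equal(reg$k, k_hat, tolerance = 1e-10)
  expect_equal(reg$s, s_hat, tolerance = 1e-10)
  expect_true(reg$informative)
})

test_that("a noiseless linear score is flagged degenerate", {
  ca <- seq(40, 70, by = 5)
  reg <- fit_age_regressions(cbind(PC1 = 0.1 * ca), ca)
  expect_equal(reg$q, 0, tolerance = 1e-10)
  expect_equal(reg$k, 0.1, tolerance = 1e-10)
  expect_lt(reg$s, 1e-10)
  expect_false(reg$informative)
})

test_that("a score independent of age has slope within 3 SE of zero", {
  set.seed(109)
  n <- 10000
  ca <- runif(n, 40, 70)
  score <- rnorm(n)
  reg <- fit_age_regressions(cbind(PC1 = score), ca)
  se <- 1 / (sd(ca) * sqrt(n))
  expect_lt(abs(reg$k), 3 * se)
})

test_that("degenerate regression inputs error", {
  expect_error(fit_age_regressions(cbind(x = 1:2), c(50, 60)), "3 fit rows")
  expect_error(fit_age_regressions(cbind(x = rnorm(10)), rep(50, 10)),
               "zero variance")
})

test_that("closed-form biological ages on one- and two-component models", {
  # single component q=0, k=1, s=1: BA inverts the score directly
  m1 <- list(
    regressions = tibble::tibble(component = "PC1", q = 0, k = 1, s = 1,
                                 n_fit = 10, informative = TRUE, w = 1),
    denom = 1, ca_correction = FALSE, s_ba2 = NA_real_
  )
  class(m1) <- "bioage_kdm"
  expect_equal(compute_ba(cbind(PC1 = 55), m1), 55)

  # two components (q,k,s) = (0,1,1) and (0,2,2), x = (50, 60)
  reg <- tibble::tibble(component = c("PC1", "PC2"), q = c(0, 0),
                        k = c(1, 2), s = c(1, 2), n_fit = 10,
                        informative = TRUE)
  denom <- sum(reg$k^2 / reg$s^2)  # 1 + 1 = 2
  reg$w <- (reg$k / reg$s^2) / denom
  m2 <- structure(list(regressions = reg, denom = denom,
                       ca_correction = FALSE, s_ba2 = NA_real_),
                  class = "bioage_kdm")
  expect_equal(compute_ba(cbind(PC1 = 50, PC2 = 60), m2),
               (50 * 1 + 60 * 0.5) / 2)
  expect_equal(compute_ba(cbind(PC1 = 50, PC2 = 60), m2), 40)
})

test_that("every fitted model is calibration-consistent: sum(w * k) = 1", {
  set.seed(113)
  for (i in 1:5) {
    sim <- kdm_consistent_scores(200, q = rnorm(4), k = runif(4, 0.02, 0.2),
                                 s = runif(4, 0.5, 2), seed = 113 + i)
    model <- fit_kdm(sim$scores, sim$ca)
    reg <- model$regressions
    expect_equal(sum(reg$w * reg$k), 1, tolerance = 1e-10)
  }
})

test_that("biological age is invariant to rescaling a score column", {
  sim <- kdm_consistent_scores(500, q = c(0, 1, -1), k = c(0.05, 0.1, 0.08),
                               s = c(1, 1.5, 0.8), seed = 127)
  m <- fit_kdm(sim$scores, sim$ca)
  ba <- compute_ba(sim$scores, m)
  scaled <- dplyr::mutate(sim$scores, PC2 = 10 * PC2)
  m2 <- fit_kdm(scaled, sim$ca)
  expect_equal(compute_ba(scaled, m2), ba, tolerance = 1e-10)
})

test_that("non-informative components are dropped with a warning", {
  sim <- kdm_consistent_scores(300, q = c(0, 0), k = c(0.1, 0.08),
                               s = c(1, 1), seed = 131)
  scores <- dplyr::mutate(sim$scores, PC3 = 0.05 * sim$ca)  # s ~ 0
  expect_warning(fit_kdm(scores, sim$ca), "non-informative")
  flat <- tibble::tibble(PC1 = 0.02 * sim$ca)
  expect_error(quiet(fit_kdm(dplyr::mutate(flat, PC1 = PC1 * 0), sim$ca)),
               "no usable components")
})

test_that("r-squared behaves at the closed-form limits", {
  set.seed(137)
  ca <- runif(5000, 40, 70)
  expect_equal(ba_r_squared(ca, ca), 1)
  expect_equal(ba_r_squared(2 * ca + 7, ca), 1)
  noise <- rnorm(5000)
  expect_lt(ba_r_squared(noise, ca), (3 / sqrt(5000))^2)
  expect_true(is.na(ba_r_squared(rep(1, 5000), ca)))
})

test_that("importance shares: closed-form cases and Monte-Carlo oracle", {
  # single component: share 1
  sim1 <- kdm_consistent_scores(300, q = 0, k = 0.1, s = 1, seed = 139)
  m1 <- fit_kdm(sim1$scores, sim1$ca)
  expect_equal(component_importance(m1)$share, 1)

  # symmetric two-component model: shares (0.5, 0.5)
  sim2 <- kdm_consistent_scores(2000, q = c(0, 0), k = c(0.1, 0.1),
                                s = c(1, 1), seed = 149)
  m2 <- fit_kdm(sim2$scores, sim2$ca)
  # force exactly equal weights/variances (fitted ones differ by sampling noise)
  m2$regressions$w <- rep(m2$regressions$w[1], 2)
  m2$score_variances[] <- mean(m2$score_variances)
  expect_equal(component_importance(m2)$share, c(0.5, 0.5))

  # three-component fixture vs brute-force Monte-Carlo variance decomposition
  sim3 <- kdm_consistent_scores(3000, q = c(1, -2, 0), k = c(0.05, 0.12, 0.08),
                                s = c(1.2, 0.7, 1.5), seed = 151)
  m3 <- fit_kdm(sim3$scores, sim3$ca)
  imp <- component_importance(m3)
  w <- m3$regressions$w
  v <- m3$score_variances
  set.seed(157)
  draws <- vapply(seq_along(w), function(j) {
    w[j] * rnorm(1e6, 0, sqrt(v[j]))
  }, numeric(1e6))
  total <- var(rowSums(draws))
  mc_share <- apply(draws, 2, var) / total
  names(mc_share) <- m3$regressions$component
  expect_equal(setNames(imp$share, imp$component),
               sort(mc_share, decreasing = TRUE), tolerance = 1e-3)
  expect_equal(sum(imp$share), 1, tolerance = 1e-6)
})

test_that("calibration table: exact identities and shifted biological age", {
  set.seed(163)
  ca <- runif(2000, 40, 70)
  tab <- calibration_table(ca, ca, origin = 40)
  expect_equal(tab$mean_ba, tab$mean_ca)
  expect_equal(tab$bin_start, seq(40, 67.5, by = 2.5))
  tab5 <- calibration_table(ca + 5, ca, origin = 40)
  expect_equal(tab5$mean_ba - tab5$mean_ca, rep(5, nrow(tab5)))
})

test_that("calibration of a KDM-consistent cohort is within a year per bin", {
  sim <- kdm_consistent_scores(10000, q = c(0, 5, -3, 1),
                               k = c(0.08, 0.1, -0.06, 0.05),
                               s = c(1, 1.2, 0.9, 1.1), seed = 167)
  m <- fit_kdm(sim$scores, sim$ca)
  ba <- compute_ba(sim$scores, m)
  tab <- calibration_table(ba, sim$ca, origin = 40)
  expect_true(all(abs(tab$mean_ba - tab$mean_ca) < 1))
})

test_that("age-acceleration groups use closed boundaries and tail fractions", {
  grp <- age_acceleration_groups(c(45, 50, 56), c(50, 50, 50))$group
  expect_equal(as.character(grp), c("younger", "similar", "older"))
  # exact -5 boundary is "younger" ("at least 5 years")
  expect_equal(as.character(age_acceleration_groups(45, 50)$group), "younger")
  expect_equal(as.character(age_acceleration_groups(55, 50)$group), "older")

  all_same <- age_acceleration_groups(rep(50, 10), rep(50, 10))
  expect_equal(all_same$fractions$fraction, c(0, 1, 0))

  # BA - CA ~ N(0, sigma): P(tail) from the normal CDF
  set.seed(173)
  n <- 10000
  sigma <- 5 / qnorm(1 - 0.171)  # tail of 17.1% at 5 years
  ca <- runif(n, 40, 70)
  ba <- ca + rnorm(n, 0, sigma)
  fr <- age_acceleration_groups(ba, ca)$fractions
  p <- 0.171
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(fr$fraction[fr$group == "younger"] - p), 3 * se)
  expect_lt(abs(fr$fraction[fr$group == "older"] - p), 3 * se)
})

test_that("biological age recovers the latent age better than chronological age", {
  sim <- kdm_consistent_scores(10000, q = rnorm(12),
                               k = runif(12, 0.04, 0.12) * sample(c(-1, 1), 12, TRUE),
                               s = runif(12, 0.6, 1.4), sigma_delta = 5, seed = 179)
  m <- fit_kdm(sim$scores, sim$ca)
  ba <- compute_ba(sim$scores, m)
  expect_gt(cor(ba, sim$ba_true), cor(sim$ca, sim$ba_true))
})

test_that("recovery error shrinks as residual noise shrinks", {
  k <- runif(8, 0.05, 0.12)
  s0 <- runif(8, 0.8, 1.2)
  rmse <- vapply(c(1, 0.5, 0.25), function(scale) {
    sim <- kdm_consistent_scores(10000, q = rep(0, 8), k = k, s = s0 * scale,
                                 sigma_delta = 5, seed = 181)
    m <- fit_kdm(sim$scores, sim$ca)
    sqrt(mean((compute_ba(sim$scores, m) - sim$ba_true)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("the CA-corrected variant shrinks BA towards CA", {
  sim <- kdm_consistent_scores(5000, q = c(0, 0, 0), k = c(0.05, 0.08, 0.06),
                               s = c(1, 1, 1), seed = 191)
  m0 <- fit_kdm(sim$scores, sim$ca)
  m1 <- fit_kdm(sim$scores, sim$ca, ca_correction = TRUE)
  expect_true(m1$ca_correction)
  expect_lt(m1$ba_sd_diff, m0$ba_sd_diff)
  expect_error(compute_ba(sim$scores, m1), "ca")
})
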