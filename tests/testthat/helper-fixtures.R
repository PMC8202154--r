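# Small configurations reused across tests. Fixtures are built in code; no
# files are read.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

small_config <- function(n = 500, seed = 42, ...) {
  sim_config(n_participants = n, seed = seed, ...)
}

big_config <- function(seed = 42, ...) {
  sim_config(n_participants = 10000, seed = seed, ...)
}

# cohort whose scores follow the KDM generative model exactly:
# score_j = q_j + k_j * ba_true + N(0, s_j^2), ba_true = ca + delta
kdm_consistent_scores <- function(n, q, k, s, sigma_delta = 5,
                                  age_range = c(40, 70), seed = 1) {
  set.seed(seed)
  ca <- runif(n, age_range[1], age_range[2])
  ba_true <- ca + rnorm(n, 0, sigma_delta)
  scores <- vapply(seq_along(k), function(j) {
    q[j] + k[j] * ba_true + rnorm(n, 0, s[j])
  }, numeric(n))
  colnames(scores) <- paste0("PC", seq_along(k))
  list(ca = ca, ba_true = ba_true, scores = tibble::as_tibble(scores))
}

# Breslow/no-ties Cox partial log-likelihood for a single covariate,
# vectorised over beta: the independent oracle for fit_cox
cox_pll_1cov <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; event <- event[ord]
  n <- length(x)
  vapply(beta, function(b) {
    eta <- b * x
    ll <- 0
    for (i in seq_len(n)) {
      if (event[i] == 1) {
        ll <- ll + eta[i] - log(sum(exp(eta[i:n])))
      }
    }
    ll
  }, numeric(1))
}

# O(n^2) Harrell concordance oracle: pairs comparable when the earlier time
# is an event; tied scores get 0.5; pairs tied on time are incomparable when
# both are events, and comparable (event ranks earlier) when one is censored
c_index_oracle <- function(score, time, event) {
  n <- length(score)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] + event[j] != 1) next  # both events or both censored
        a <- if (event[i] == 1) i else j    # the event member "fails first"
        b <- if (event[i] == 1) j else i
      } else {
        a <- if (time[i] < time[j]) i else j
        b <- if (time[i] < time[j]) j else i
        if (event[a] != 1) next
      }
      den <- den + 1
      if (score[a] > score[b]) num <- num + 1
      else if (score[a] == score[b]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}
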