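# Independent oracles used by the test suite.  These deliberately avoid the
# package's fitting path (and the survival package) so agreement is a real
# cross-check.

# Efron partial log-likelihood of a single covariate evaluated on a grid of
# beta values.  Handles tied event times by the Efron correction; reduces
# to the exact partial likelihood when times are distinct.
efron_loglik_grid <- function(time, event, x, betas) {
  E <- exp(outer(x, betas))              # n x G
  ll <- numeric(length(betas))
  for (tau in sort(unique(time[event == 1]))) {
    R <- time >= tau
    D <- event == 1 & time == tau
    d <- sum(D)
    sR <- colSums(E[R, , drop = FALSE])
    sD <- colSums(E[D, , drop = FALSE])
    ll <- ll + betas * sum(x[D])
    for (k in seq_len(d) - 1L) ll <- ll - log(sR - (k / d) * sD)
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood.
grid_search_cox_beta <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  betas <- seq(lo, hi, by = step)
  betas[which.max(efron_loglik_grid(time, event, x, betas))]
}

# Hand tabulation of the unweighted k-group logrank statistic: observed
# minus expected events per group at each distinct event time, with the
# hypergeometric variance, combined into the chi-square form.
logrank_by_hand <- function(time, event, group) {
  g <- factor(group)
  k <- nlevels(g)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (tau in sort(unique(time[event == 1]))) {
    at_risk <- time >= tau
    n <- sum(at_risk)
    d <- sum(event == 1 & time == tau)
    n_g <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    d_g <- vapply(levels(g), function(l) sum(event == 1 & time == tau & g == l),
                  numeric(1))
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      cf <- d * (n - d) / (n - 1)
      for (i in seq_len(k)) for (j in seq_len(k)) {
        V[i, j] <- V[i, j] + cf *
          (if (i == j) n_g[i] / n * (1 - n_g[i] / n) else -n_g[i] * n_g[j] / n^2)
      }
    }
  }
  u <- (O - E)[-1]
  chisq <- drop(t(u) %*% solve(V[-1, -1, drop = FALSE]) %*% u)
  list(chi_square = chisq, df = k - 1)
}

# Dataset generator for the Cox oracle checks: one binary covariate,
# continuous or lightly tied event times, some censoring.
make_cox_oracle_data <- function(seed, n = 30, tie = FALSE) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  beta <- runif(1, -1.5, 1.5)
  t_event <- rexp(n, rate = 0.5 * exp(beta * x))
  if (tie) t_event <- ceiling(t_event * 4) / 4   # force tied event times
  cens <- runif(n, 0.5, 6)
  list(time = pmin(t_event, cens), event = as.numeric(t_event <= cens), x = x)
}
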