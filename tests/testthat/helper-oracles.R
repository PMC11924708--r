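# Independent numerical oracles used across the test files.

# Brute-force grid posterior for the hierarchical binomial/logit-normal
# model: p(mu, tau | data) on a rectangular grid, with the per-study random
# effect integrated out by Gauss-Hermite quadrature. Returns the predictive
# mean of inverse-logit(mu + tau * z), z ~ N(0, 1), computed by the same
# quadrature. Priors match fit_map_hierarchical(): mu ~ N(mu_mean, mu_sd^2),
# tau ~ Half-Normal(tau_scale).
grid_map_predictive_mean <- function(studies, mu_mean = 0, mu_sd = 2,
                                     tau_scale = 1, n_mu = 241, n_tau = 121,
                                     n_z = 401) {
  # standard-normal integrals over z by trapezoid on a wide fixed grid
  # (robust to likelihood peaks far from z = 0 at large tau)
  z <- seq(-8, 8, length.out = n_z)
  wz <- c(diff(z)[1] / 2, (diff(z)[-1] + diff(z)[-(n_z - 1)]) / 2,
          diff(z)[n_z - 1] / 2) * stats::dnorm(z)
  mu_grid <- seq(mu_mean - 4 * mu_sd, mu_mean + 4 * mu_sd, length.out = n_mu)
  tau_grid <- seq(1e-4, 5 * tau_scale, length.out = n_tau)
  y <- studies$n_events
  n <- studies$n_patients

  log_lik <- function(mu, tau) {
    th <- stats::plogis(mu + tau * z)
    sum(vapply(seq_along(y), function(jj) {
      log(sum(wz * stats::dbinom(y[jj], n[jj], th)))
    }, numeric(1)))
  }
  lp <- outer(seq_along(mu_grid), seq_along(tau_grid),
              Vectorize(function(i, k) {
                log_lik(mu_grid[i], tau_grid[k]) +
                  stats::dnorm(mu_grid[i], mu_mean, mu_sd, log = TRUE) +
                  stats::dnorm(tau_grid[k], 0, tau_scale, log = TRUE)
              }))
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  pred <- outer(seq_along(mu_grid), seq_along(tau_grid),
                Vectorize(function(i, k) {
                  sum(wz * stats::plogis(mu_grid[i] + tau_grid[k] * z))
                }))
  sum(post * pred)
}

# Monte-Carlo oracle for the expected local information ratio of a beta
# mixture (binomial unit information), with its standard error.
mc_elir <- function(mix, n_draws = 1e6, seed = 99) {
  set.seed(seed)
  th <- rmix(mix, n_draws)
  a <- mix$alpha; b <- mix$beta; w <- mix$weights
  P <- sapply(seq_along(a), function(k) w[k] * stats::dbeta(th, a[k], b[k]))
  G <- sapply(seq_along(a), function(k) (a[k] - 1) / th - (b[k] - 1) / (1 - th))
  Gp <- sapply(seq_along(a),
               function(k) -(a[k] - 1) / th^2 - (b[k] - 1) / (1 - th)^2)
  p <- rowSums(P); p1 <- rowSums(P * G); p2 <- rowSums(P * (G^2 + Gp))
  lir <- ((p1 / p)^2 - p2 / p) * th * (1 - th)
  list(est = mean(lir), se = stats::sd(lir) / sqrt(n_draws))
}

# Monte-Carlo oracle for Pr(theta_t - theta_c < M) under independent
# beta-mixture posteriors.
mc_prob_noninf <- function(test_mix, control_mix, margin, n_draws = 1e6,
                           seed = 5) {
  set.seed(seed)
  tt <- rmix(test_mix, n_draws)
  cc <- rmix(control_mix, n_draws)
  p <- mean(tt - cc < margin)
  list(est = p, se = sqrt(p * (1 - p) / n_draws))
}

# direct log-likelihood-ratio computation of the congruence weight,
# independent of sam_weight()
direct_sam_weight <- function(y, n, theta_hat, delta) {
  ll <- function(p) dbinom(y, n, p, log = TRUE)
  r <- exp(ll(theta_hat) - max(ll(theta_hat + delta), ll(theta_hat - delta)))
  r / (1 + r)
}

# shared fixtures
printed_map_em <- function() {
  beta_mixture(c(10.59, 4.53), c(54.71, 17.92), c(0.58, 0.42))
}
printed_historical <- function() {
  historical_studies(c(204, 220, 499, 60), c(30, 20, 14, 10))
}
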