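test_that("study container validates counts", {
  expect_error(historical_studies(10, 11), "n_events")
  expect_error(historical_studies(0, 0), "positive")
  h <- historical_studies(c(204, 220, 499, 60), c(30, 20, 14, 10))
  expect_equal(nrow(h), 4L)
})

test_that("heterogeneity is zero for homogeneous studies and large for extreme spread", {
  homo <- historical_studies(c(100, 100), c(20, 20))
  r <- heterogeneity_i2(homo)
  expect_equal(r$q_statistic, 0, tolerance = 1e-12)
  expect_equal(r$i_squared, 0)
  expect_equal(r$df, 1L)

  spread <- historical_studies(c(100, 100, 100), c(10, 50, 90))
  expect_gt(heterogeneity_i2(spread)$i_squared, 0.9)
})

test_that("the four published studies show about 91% heterogeneity", {
  # direct fixed-effect Q on logit proportions, computed inline as oracle
  h <- printed_historical()
  p <- h$n_events / h$n_patients
  yi <- qlogis(p)
  vi <- 1 / h$n_events + 1 / (h$n_patients - h$n_events)
  wi <- 1 / vi
  q <- sum(wi * (yi - sum(wi * yi) / sum(wi))^2)
  i2_oracle <- (q - 3) / q

  r <- heterogeneity_i2(h)
  expect_equal(r$i_squared, i2_oracle, tolerance = 1e-10)
  expect_equal(r$i_squared, 0.908, tolerance = 0.005)
  expect_lt(r$p_value, 0.001)
  # raw-proportion scale lands in the same neighbourhood
  expect_equal(heterogeneity_i2(h, "raw")$i_squared, 0.91, tolerance = 0.01)
})

test_that("heterogeneity is invariant to study relabeling and needs 2+ studies", {
  h <- printed_historical()
  perm <- h[c(3, 1, 4, 2), ]
  expect_equal(heterogeneity_i2(perm)$i_squared,
               heterogeneity_i2(h)$i_squared, tolerance = 1e-12)
  expect_error(heterogeneity_i2(h[1, , drop = FALSE]), "at least 2")
})

test_that("zero-event studies get the continuity correction and a flag", {
  h <- historical_studies(c(50, 60), c(0, 6))
  r <- heterogeneity_i2(h)
  expect_true(r$continuity_corrected)
  expect_true(is.finite(r$q_statistic))
})

test_that("hierarchical MAP fit matches a brute-force grid posterior", {
  h <- printed_historical()
  fit <- fit_map_hierarchical(h, seed = 7)
  expect_equal(fit$n_chains, 4L)
  expect_true(all(fit$draws > 0 & fit$draws < 1))
  expect_true(all(fit$diagnostics$split_rhat[1:2] < 1.01))

  oracle <- grid_map_predictive_mean(h)
  expect_lt(abs(mean(fit$draws) - oracle), 0.015)
  # predictive mean stays between the observed study proportions
  p <- h$n_events / h$n_patients
  expect_gt(mean(fit$draws), min(p))
  expect_lt(mean(fit$draws), max(p))
})

test_that("pooling limit: one study with tau pinned near zero recovers its rate", {
  fit <- fit_map_hierarchical(
    historical_studies(100, 50),
    map_mcmc_control(tau_scale = 0.01, n_adapt = 500, n_iter = 1000),
    seed = 1)
  expect_equal(mean(fit$draws), 0.5, tolerance = 0.02)
})

test_that("two identical studies agree with the grid-posterior oracle", {
  h <- historical_studies(c(100, 100), c(20, 20))
  fit <- fit_map_hierarchical(h, map_mcmc_control(n_adapt = 500, n_iter = 2000),
                              seed = 2)
  expect_lt(abs(mean(fit$draws) - grid_map_predictive_mean(h)), 0.015)
})

test_that("EM recovers single-component beta parameters within 10%", {
  set.seed(11)
  x <- rbeta(10000, 10, 50)
  m <- fit_beta_mixture_em(x, 1, seed = 1)
  expect_equal(m$alpha, 10, tolerance = 0.1)
  expect_equal(m$beta, 50, tolerance = 0.1)
})

test_that("EM recovers a separated two-component mixture", {
  set.seed(12)
  x <- c(rbeta(5000, 2, 38), rbeta(5000, 30, 70))
  m <- fit_beta_mixture_em(x, 2, seed = 1)
  expect_equal(sort(m$weights), c(0.5, 0.5), tolerance = 0.05)
  # components come back ordered by descending weight; match by mean
  means <- m$alpha / (m$alpha + m$beta)
  expect_equal(sort(means), c(2 / 40, 30 / 100), tolerance = 0.02)
  # moment matching of the ML fit
  expect_equal(mixture_mean(m), mean(x), tolerance = 0.005)
  # monotone log-likelihood across EM iterations
  expect_true(all(diff(attr(m, "loglik_trace")) > -1e-6))
})

test_that("EM input validation", {
  expect_error(fit_beta_mixture_em(runif(100)), "1000 draws")
  expect_error(fit_beta_mixture_em(c(rep(0.5, 999), 1.2), 1), "inside")
})
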