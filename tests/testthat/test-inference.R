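test_that("conjugate updating follows beta-binomial arithmetic", {
  post <- update_mixture_posterior(beta_mixture(1, 1), 3, 10)
  expect_equal(post$alpha, 4)
  expect_equal(post$beta, 8)
  # no data leaves the prior untouched
  pri <- printed_map_em()
  expect_equal(update_mixture_posterior(pri, 0, 0), pri)
})

test_that("data far from the informative component shifts the weight to the vague one", {
  pri <- beta_mixture(c(10, 1), c(50, 1), c(0.5, 0.5))
  post <- update_mixture_posterior(pri, 30, 40)
  # oracle: log marginal likelihoods m_k computed inline
  lm <- lbeta(pri$alpha + 30, pri$beta + 10) - lbeta(pri$alpha, pri$beta)
  w_oracle <- exp(lm) * 0.5 / sum(exp(lm) * 0.5)
  expect_equal(post$weights, w_oracle, tolerance = 1e-12)
  expect_gt(post$weights[2], 0.99)
})

test_that("updating commutes with pooling the data", {
  pri <- printed_map_em()
  seq_post <- update_mixture_posterior(update_mixture_posterior(pri, 7, 40),
                                       11, 60)
  pooled <- update_mixture_posterior(pri, 18, 100)
  expect_equal(seq_post$alpha, pooled$alpha)
  expect_equal(seq_post$beta, pooled$beta)
  expect_equal(seq_post$weights, pooled$weights, tolerance = 1e-12)
  expect_equal(sum(seq_post$weights), 1, tolerance = 1e-12)
})

test_that("probability of noninferiority: symmetry, separation, Monte-Carlo oracle", {
  m <- beta_mixture(c(5, 2), c(20, 8), c(0.7, 0.3))
  expect_equal(prob_noninferiority(m, m, 0), 0.5, tolerance = 1e-6)
  expect_gt(prob_noninferiority(beta_mixture(1, 1e6), beta_mixture(50, 50),
                                0.04), 0.999)
  mc <- mc_prob_noninf(beta_mixture(22, 78), beta_mixture(18, 82), 0.04,
                       n_draws = 1e6, seed = 5)
  expect_lt(abs(prob_noninferiority(beta_mixture(22, 78),
                                    beta_mixture(18, 82), 0.04) - mc$est),
            3 * mc$se)
})

test_that("probability of noninferiority matches the oracle on random posterior pairs", {
  set.seed(17)
  for (i in 1:5) {
    mt <- beta_mixture(runif(2, 2, 40), runif(2, 10, 90))
    mc_mix <- beta_mixture(runif(2, 2, 40), runif(2, 10, 90))
    m <- runif(1, 0, 0.1)
    o <- mc_prob_noninf(mt, mc_mix, m, n_draws = 4e5, seed = 100 + i)
    expect_lt(abs(prob_noninferiority(mt, mc_mix, m) - o$est),
              3 * o$se + 1e-5)
  }
})

test_that("probability of noninferiority is monotone in events and margin", {
  ctrl <- beta_mixture(18, 82)
  p_by_events <- vapply(c(10, 15, 20, 25),
                        function(y) prob_noninferiority(
                          beta_mixture(1 + y, 1 + 100 - y), ctrl, 0.04),
                        numeric(1))
  expect_true(all(diff(p_by_events) < 0))
  p_by_margin <- vapply(c(0, 0.02, 0.04, 0.08),
                        function(m) prob_noninferiority(
                          beta_mixture(22, 78), ctrl, m), numeric(1))
  expect_true(all(diff(p_by_margin) > 0))
})

test_that("decision rule applies strict thresholds with ties continuing", {
  d <- build_gs_design(design_config())
  pl <- d$prob_lower
  pu <- d$prob_upper
  expect_equal(interim_decision(0.30, d, 1)$outcome, "stop_futility")
  expect_equal(interim_decision(pl[1], d, 1)$outcome, "continue")
  expect_equal(interim_decision(pu[1], d, 1)$outcome, "continue")
  expect_equal(interim_decision(0.999, d, 1)$outcome, "stop_efficacy")
  expect_equal(interim_decision(0.8, d, 2)$outcome, "continue")
  expect_equal(interim_decision(0.96, d, 3)$outcome, "final_noninferior")
  expect_equal(interim_decision(0.94, d, 3)$outcome, "final_inferior")
  expect_error(interim_decision(0.5, d, 4), "out of range")
})

test_that("arm posterior records the absorbed data", {
  ap <- arm_posterior(beta_mixture(1, 1), 3, 12)
  expect_equal(ap$n_obs, 12L)
  expect_equal(ap$y_obs, 3L)
  expect_equal(ap$mixture$alpha, 4)
  expect_equal(prob_noninferiority(ap, ap, 0), 0.5, tolerance = 1e-6)
})
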