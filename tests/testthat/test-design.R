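test_that("Hwang-Shih-DeCani spending evaluates its closed form", {
  expect_equal(hsd_spending(0.05, -4, 1), 0.05)
  expect_equal(hsd_spending(0.05, -4, 0), 0)
  expect_equal(hsd_spending(0.05, -4, 1 / 3), 0.0026061, tolerance = 1e-5)
  expect_equal(hsd_spending(0.2, -2, 1 / 3), 0.0296674, tolerance = 1e-5)
  # gamma -> 0 limit is linear spending
  expect_equal(hsd_spending(0.1, 0, 0.4), 0.04)
  expect_equal(hsd_spending(0.1, 1e-14, 0.4), 0.04, tolerance = 1e-9)
  expect_error(hsd_spending(0.05, -4, 1.2), "0, 1")
})

test_that("one-stage noninferiority sample size reproduces hand arithmetic", {
  # worked example: alpha 0.05, beta 0.2, control rate 0.179 rounded to
  # 0.18, margin 0.04 -> 1141 per arm, 2282 total
  expect_equal(one_stage_sample_size(design_config()), 2282L)
  # hand case: (1.6449 + 0.8416)^2 * 2 * 0.25 / 0.25 = 12.4 -> 13 per arm
  cfg <- design_config(theta_control = 0.5, margin_m = 0.5)
  expect_equal(one_stage_sample_size(cfg), 26L)
  # n scales as 1 / M^2 before rounding
  n1 <- one_stage_sample_size(design_config(margin_m = 0.02, rate_digits = NULL))
  n2 <- one_stage_sample_size(design_config(margin_m = 0.04, rate_digits = NULL))
  expect_equal(n1 / n2, 4, tolerance = 0.01)
  expect_error(design_config(margin_m = 0), "positive")
})

test_that("worked-example boundaries and inflated sample size are reproduced", {
  d <- build_gs_design(design_config())
  expect_equal(round(d$z_upper, 2), c(2.79, 2.29, 1.64))
  expect_equal(round(d$z_lower, 2), c(-0.42, 0.64, 1.64))
  expect_equal(d$n_fixed, 2282L)
  expect_equal(d$n_max, 2386L)
  expect_equal(d$per_look_n, c(796L, 1591L, 2386L))
  expect_gte(d$inflation, 1)
  # bounds meet exactly at the final analysis
  expect_equal(d$z_lower[3], d$z_upper[3])
  # spending totals
  expect_equal(d$alpha_spent, 0.05, tolerance = 1e-10)
  expect_equal(d$beta_spent, 0.2, tolerance = 1e-10)
})

test_that("boundary solution is stable under grid refinement", {
  d1 <- build_gs_design(design_config(grid_points = 401))
  d2 <- build_gs_design(design_config(grid_points = 1001))
  expect_equal(d1$z_upper, d2$z_upper, tolerance = 5e-4)
  expect_equal(d1$z_lower, d2$z_lower, tolerance = 5e-4)
  expect_equal(d1$inflation, d2$inflation, tolerance = 1e-4)
})

test_that("single-look design degenerates to the fixed design", {
  d <- build_gs_design(design_config(n_analyses = 1))
  expect_equal(d$z_upper, qnorm(0.95), tolerance = 1e-9)
  expect_equal(d$inflation, 1)
  expect_equal(d$n_max, d$n_fixed)
})

test_that("probability bounds are Phi of the Z bounds and preserve order", {
  pb <- z_to_probability_bounds(c(-0.42, 0.64, 1.64), c(2.79, 2.29, 1.64))
  expect_equal(round(pb$prob_lower, 3), c(0.337, 0.739, 0.949))
  expect_equal(round(pb$prob_upper[1:2], 3), c(0.997, 0.989))
  expect_equal(z_to_probability_bounds(0, 0)$prob_lower, 0.5)
  z <- sort(rnorm(5))
  expect_true(all(diff(z_to_probability_bounds(z, z)$prob_lower) > 0))
  expect_error(z_to_probability_bounds(Inf, 1), "finite")
})

test_that("recursive integration matches a bivariate-normal Monte-Carlo oracle", {
  d <- build_gs_design(design_config(n_analyses = 2))
  a_inc <- diff(c(0, hsd_spending(0.05, -4, c(0.5, 1))))
  set.seed(3)
  n <- 1e6
  w1 <- rnorm(n, 0, sqrt(0.5))
  z1 <- w1 / sqrt(0.5)
  z2 <- w1 + rnorm(n, 0, sqrt(0.5))  # correlation sqrt(1/2) between looks
  p1 <- mean(z1 > d$z_upper[1])
  p2 <- mean(z1 <= d$z_upper[1] & z1 >= d$z_lower[1] & z2 > d$z_upper[2])
  se1 <- sqrt(a_inc[1] * (1 - a_inc[1]) / n)
  se2 <- sqrt(a_inc[2] * (1 - a_inc[2]) / n)
  expect_lt(abs(p1 - a_inc[1]), 3 * se1)
  expect_lt(abs(p2 - a_inc[2]), 3 * se2)
})

test_that("four-analysis configuration is a config change, not new code", {
  d <- build_gs_design(design_config(n_analyses = 4))
  expect_length(d$z_upper, 4)
  expect_true(all(diff(d$z_upper) < 0))
  expect_true(all(diff(d$z_lower) > 0))
  expect_equal(d$z_lower[4], d$z_upper[4])
  expect_gte(d$inflation, 1)
})
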