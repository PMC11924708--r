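test_that("allocation probability covers both arithmetic branches", {
  expect_equal(allocation_probability(398, 398, 16), 0.48975, tolerance = 1e-4)
  expect_equal(allocation_probability(398, 398, 0), 0.5)
  expect_equal(allocation_probability(100, 100, 100), 0)
  expect_equal(allocation_probability(100, 100, 250), 0)
  r <- max(300 - 40, 0) / 300
  expect_equal(allocation_probability(300, 300, 40), r / (r + 1))
})

test_that("scenario grid crosses incongruence offsets with both hypotheses", {
  sc <- default_scenarios(0.179, 0.02, 0.04)
  expect_equal(nrow(sc), 8L)
  expect_equal(sc$theta_c[5], 0.149)
  expect_equal(sc$theta_t[5], 0.189)
  expect_equal(sc$theta_c[1], 0.179)
  expect_equal(sc$theta_t[1], 0.219)
  expect_equal(sc$theta_t[sc$hypothesis == "H1"],
               sc$theta_c[sc$hypothesis == "H1"])
  expect_equal(sc$theta_t[sc$hypothesis == "H0"],
               sc$theta_c[sc$hypothesis == "H0"] + 0.04)
  expect_true(all(default_scenarios(0.179, 0, 0.04)$theta_c == 0.179))
})

gs_fixture <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- build_gs_design(design_config())
    d
  }
})

test_that("an extremely inferior test device stops early for futility", {
  cfg <- trial_config(gs_fixture(), printed_map_em())
  res <- lapply(1:20, function(j) simulate_trial(
    cfg, list(theta_c = 0.179, theta_t = 0.999), seed = j))
  expect_true(all(!vapply(res, `[[`, logical(1), "rejected")))
  expect_true(all(vapply(res, `[[`, numeric(1), "stop_look") == 1))
})

test_that("disabling borrowing gives a zero weight trace and the weak prior's ESS", {
  cfg <- trial_config(gs_fixture(), printed_map_em(),
                      weight_mode = "fixed", fixed_weight = 0)
  res <- simulate_trial(cfg, list(theta_c = 0.179, theta_t = 0.179), seed = 4)
  w <- res$per_look$w
  ess <- res$per_look$ess
  expect_true(all(w[!is.na(w)] == 0))
  weak_ess <- elir_ess(weak_prior(0.179))$ess
  expect_true(all(abs(ess[!is.na(ess)] - weak_ess) < 1e-6))
})

test_that("a frozen half weight yields a constant weight trace", {
  cfg <- trial_config(gs_fixture(), printed_map_em(),
                      weight_mode = "fixed", fixed_weight = 0.5)
  res <- lapply(1:10, function(j) simulate_trial(
    cfg, list(theta_c = 0.179, theta_t = 0.179), seed = 100 + j))
  w <- unlist(lapply(res, function(r) r$per_look$w))
  expect_true(all(w[!is.na(w)] == 0.5))
})

test_that("trial bookkeeping conserves enrollment within design limits", {
  cfg <- trial_config(gs_fixture(), printed_map_em())
  d <- gs_fixture()
  for (j in 1:30) {
    r <- simulate_trial(cfg, list(theta_c = 0.169, theta_t = 0.189),
                        seed = 500 + j)
    expect_equal(sum(r$per_look$enrolled_new), r$total_enrolled)
    expect_equal(r$n_control + r$n_test, r$total_enrolled)
    expect_lte(r$total_enrolled, d$n_max)
    expect_gte(r$total_enrolled, d$per_look_n[1])
    expect_lte(r$stop_look, 3)
    w <- r$per_look$w
    expect_true(all(w[!is.na(w)] >= 0 & w[!is.na(w)] <= 1))
    ess <- r$per_look$ess
    expect_true(all(ess[!is.na(ess)] <=
                      elir_ess(printed_map_em())$ess + 1e-6))
  }
})

test_that("operating characteristics are reproducible bitwise for a fixed seed", {
  cfg <- trial_config(gs_fixture(), printed_map_em())
  sc <- default_scenarios()[c(1, 4), ]
  oc1 <- run_scenarios(cfg, sc, n_sims = 15, seed = 42)
  oc2 <- run_scenarios(cfg, sc, n_sims = 15, seed = 42)
  expect_identical(oc1, oc2)
  oc3 <- run_scenarios(cfg, sc, n_sims = 15, seed = 43)
  expect_false(identical(oc1$rejection_rate, oc3$rejection_rate) &&
                 identical(oc1$enrolled_mean, oc3$enrolled_mean))
})

test_that("degenerate single-simulation summaries collapse to point values", {
  cfg <- trial_config(gs_fixture(), printed_map_em())
  oc <- run_scenarios(cfg, default_scenarios()[2, ], n_sims = 1, seed = 7)
  expect_true(oc$rejection_rate %in% c(0, 1))
  expect_equal(oc$enrolled_q25, oc$enrolled_q75)
  expect_equal(oc$enrolled_mean, oc$enrolled_q25)
})
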