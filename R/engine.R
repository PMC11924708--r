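#' Control-arm assignment probability under ESS-reduced enrollment
#'
#' After an interim, the next stage's control enrollment target is reduced
#' by the prior's effective sample size: with `r = max(n_c_planned - ess,
#' 0) / n_t_planned`, each newly enrolled patient is assigned to the
#' control arm with probability `r / (r + 1)`. With `ess = 0` this is the
#' balanced 0.5; once `ess >= n_c_planned` every new patient goes to the
#' test arm.
#'
#' @param n_c_planned control patients planned for the stage (positive).
#' @param n_t_planned test patients planned for the stage (positive).
#' @param ess prior effective sample size (non-negative).
#' @return The control-assignment probability in `[0, 1]`.
#' @examples
#' allocation_probability(398, 398, 16)  # ~0.490
#' @export
allocation_probability <- function(n_c_planned, n_t_planned, ess) {
  stopifnot(n_c_planned > 0, n_t_planned > 0, ess >= 0)
  r <- max(n_c_planned - ess, 0) / n_t_planned
  r / (r + 1)
}

#' Scenario grid for the operating-characteristics study
#'
#' The eight-scenario grid crossing increasing historical/current control
#' incongruence with the null and alternative hypotheses: the true current
#' control rate takes offsets `{0, -delta, -3 delta/2, -2 delta}` from the
#' historical rate, and the true test rate is `theta_c + margin_m` under H0
#' (an exactly-at-the-margin inferior device) or `theta_c` under H1 (an
#' identical device).
#'
#' @param theta_h historical control rate (MAP estimate).
#' @param delta congruence margin; `theta_h - 2 * delta` must stay positive.
#' @param margin_m noninferiority margin.
#' @return A `data.frame` with columns `id`, `congruent`, `hypothesis`,
#'   `theta_h`, `theta_c`, `theta_t`, `delta`, `margin_m`.
#' @examples
#' default_scenarios(0.179, 0.02, 0.04)
#' @export
default_scenarios <- function(theta_h = 0.179, delta = 0.02, margin_m = 0.04) {
  stopifnot(theta_h - 2 * delta > 0, margin_m > 0)
  offs <- rep(c(0, -delta, -1.5 * delta, -2 * delta), each = 2)
  hyp <- rep(c("H0", "H1"), times = 4)
  theta_c <- theta_h + offs
  theta_t <- ifelse(hyp == "H0", theta_c + margin_m, theta_c)
  data.frame(id = 1:8, congruent = offs == 0, hypothesis = hyp,
             theta_h = theta_h, theta_c = theta_c, theta_t = theta_t,
             delta = delta, margin_m = margin_m)
}

#' Trial configuration for the simulation engine
#'
#' Everything a simulated trial needs besides the true rates: the
#' group-sequential design, the informative MAP-EM mixture, the historical
#' point estimate and congruence margin, and the borrowing mode.
#'
#' @param design a [build_gs_design()] result.
#' @param map_em the informative MAP-EM [beta_mixture()].
#' @param theta_h_hat historical control point estimate (MAP-EM mixture
#'   mean), fixed at design time; defaults to `mixture_mean(map_em)`.
#' @param delta congruence margin for [sam_weight()].
#' @param margin_m noninferiority margin.
#' @param weight_mode `"adaptive"` (SAM weight recomputed from cumulative
#'   control data at each interim) or `"fixed"` (frozen `fixed_weight`).
#' @param fixed_weight weight used when `weight_mode = "fixed"`.
#' @param ess_weak information content of the weak prior component.
#' @param weak_unit_information passed to [weak_prior()].
#' @param test_prior prior [beta_mixture()] of the test arm; default
#'   uniform `Beta(1, 1)`.
#' @param fisher unit-information convention for [elir_ess()].
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(design, map_em, theta_h_hat = NULL, delta = 0.02,
                         margin_m = 0.04,
                         weight_mode = c("adaptive", "fixed"),
                         fixed_weight = 0.5, ess_weak = 1,
                         weak_unit_information = TRUE,
                         test_prior = beta_mixture(1, 1),
                         fisher = "binomial") {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(design, "gs_design"), inherits(map_em, "beta_mixture"))
  if (is.null(theta_h_hat)) theta_h_hat <- mixture_mean(map_em)
  if (weight_mode == "fixed" &&
      (!is.numeric(fixed_weight) || fixed_weight < 0 || fixed_weight > 1))
    stop("'fixed_weight' must be in [0, 1] when weight_mode = 'fixed'")
  weak <- weak_prior(theta_h_hat, ess_weak, weak_unit_information)
  structure(list(design = design, map_em = map_em, theta_h_hat = theta_h_hat,
                 delta = delta, margin_m = margin_m, weight_mode = weight_mode,
                 fixed_weight = fixed_weight, weak = weak,
                 test_prior = test_prior, fisher = fisher),
            class = "trial_config")
}

#' Simulate one group-sequential trial with SAM-prior borrowing
#'
#' Runs the full interim algorithm. Stage 1 enrolls the first planned block
#' split 1:1 (exact halves), draws binomial outcomes at the scenario's true
#' rates, and tests with the weakly informative priors only (no borrowing
#' before the first congruence assessment). At each continuation interim
#' the congruence weight is computed from the cumulative control data (or
#' frozen, in fixed mode), the SAM prior is assembled and its ELIR ESS
#' taken; the next stage then enrolls its planned increment reduced by the
#' rounded ESS, with each patient assigned to control with the probability
#' from [allocation_probability()]. Posteriors always absorb all cumulative
#' data; the control prior from the second analysis on is the current SAM
#' prior, the test prior stays as configured.
#'
#' Uses the current RNG state unless `seed` is given.
#'
#' @param cfg a [trial_config()].
#' @param scenario one row of [default_scenarios()] (or any list with
#'   `theta_c` and `theta_t`).
#' @param seed optional integer seed.
#' @return A list of class `trial_result`: `outcome`, `rejected` (H0
#'   rejected, i.e. efficacy stop or final noninferiority), `stop_look`,
#'   `total_enrolled`, `n_control`, `n_test`, and the `per_look` trace
#'   (`look`, `w`, `ess`, `p`, `n_control`, `n_test`, `enrolled_new`).
#' @export
simulate_trial <- function(cfg, scenario, seed = NULL) {
  stopifnot(inherits(cfg, "trial_config"))
  if (!is.null(seed)) set.seed(seed)
  design <- cfg$design
  K <- length(design$z_upper)
  per_look <- design$per_look_n
  theta_c <- scenario$theta_c
  theta_t <- scenario$theta_t

  n_c <- y_c <- n_t <- y_t <- 0L
  control_prior <- cfg$weak
  w_k <- NA_real_
  ess_k <- NA_real_
  trace <- vector("list", K)
  outcome <- NA_character_
  stop_look <- K

  for (k in seq_len(K)) {
    inc_planned <- per_look[k] - if (k == 1L) 0L else per_look[k - 1L]
    if (k == 1L) {
      n_c_new <- inc_planned %/% 2L
      n_t_new <- inc_planned - n_c_new
    } else {
      inc <- max(inc_planned - as.integer(round(ess_k)), 0L)
      q <- allocation_probability(inc_planned / 2, inc_planned / 2, ess_k)
      n_c_new <- stats::rbinom(1L, inc, q)
      n_t_new <- inc - n_c_new
    }
    y_c_new <- stats::rbinom(1L, n_c_new, theta_c)
    y_t_new <- stats::rbinom(1L, n_t_new, theta_t)
    n_c <- n_c + n_c_new; y_c <- y_c + y_c_new
    n_t <- n_t + n_t_new; y_t <- y_t + y_t_new

    post_c <- update_mixture_posterior(control_prior, y_c, n_c)
    post_t <- update_mixture_posterior(cfg$test_prior, y_t, n_t)
    p <- prob_noninferiority(post_t, post_c, cfg$margin_m)
    dec <- interim_decision(p, design, k)

    # w/ess columns hold the congruence assessment made AT this interim
    # (NA when the trial stops here and none is made)
    trace[[k]] <- data.frame(look = k, w = NA_real_, ess = NA_real_, p = p,
                             n_control = n_c, n_test = n_t,
                             enrolled_new = n_c_new + n_t_new)
    if (dec$outcome != "continue") {
      outcome <- dec$outcome
      stop_look <- k
      break
    }
    # congruence assessment feeding the next stage
    w_k <- if (cfg$weight_mode == "adaptive")
      sam_weight(y_c, n_c, cfg$theta_h_hat, cfg$delta)
    else cfg$fixed_weight
    control_prior <- build_sam_prior(w_k, cfg$map_em, cfg$weak)
    ess_k <- elir_ess(control_prior, fisher = cfg$fisher)$ess
    trace[[k]]$w <- w_k
    trace[[k]]$ess <- ess_k
  }
  per_look_df <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  structure(list(outcome = outcome,
                 rejected = outcome %in% c("stop_efficacy", "final_noninferior"),
                 stop_look = stop_look,
                 total_enrolled = n_c + n_t, n_control = n_c, n_test = n_t,
                 per_look = per_look_df),
            class = "trial_result")
}

trial_stream_seed <- function(seed, scenario_index, trial_index) {
  # deterministic Lehmer-style substream below 2^31
  s <- (abs(seed) * 1009 + scenario_index * 1000003 + trial_index * 48271) %%
    2147483647
  as.integer(s) + 1L
}

iqr_lo <- function(x) unname(stats::quantile(x, 0.25, na.rm = TRUE, type = 7))
iqr_hi <- function(x) unname(stats::quantile(x, 0.75, na.rm = TRUE, type = 7))

#' Operating characteristics over a scenario grid
#'
#' Simulates `n_sims` independent trials per scenario (deterministic
#' per-trial seed substreams keyed by the master seed, the scenario index
#' and the trial index) and aggregates the rejection rate -- the type I
#' error rate under H0 scenarios, power under H1 scenarios -- together with
#' enrollment, effective sample size, early-stopping percentages, and the
#' congruence weight at each interim (means and interquartile ranges).
#'
#' @param cfg a [trial_config()].
#' @param scenarios a scenario grid, see [default_scenarios()].
#' @param n_sims simulated trials per scenario.
#' @param seed master integer seed.
#' @return A `data.frame` of class `sam_oc`, one row per scenario, with
#'   columns `scenario`, `hypothesis`, `congruent`, `theta_c`, `theta_t`,
#'   `rejection_rate`, `enrolled_mean`/`_q25`/`_q75`,
#'   `ess_mean`/`_q25`/`_q75` (per-trial mean SAM-prior ESS over interims
#'   reached), `pct_stop_1`, `pct_stop_2` (percent stopping early at the
#'   first/second interim), `w1_*` and `w2_*` (congruence weight at the
#'   first/second interim among trials reaching it), and `n_sims`.
#' @examples
#' \donttest{
#' d <- build_gs_design(design_config())
#' m <- beta_mixture(c(10.59, 4.53), c(54.71, 17.92), c(0.58, 0.42))
#' cfg <- trial_config(d, m)
#' run_scenarios(cfg, default_scenarios()[1:2, ], n_sims = 20, seed = 1)
#' }
#' @export
run_scenarios <- function(cfg, scenarios = default_scenarios(), n_sims = 1000,
                          seed = 1) {
  stopifnot(n_sims >= 1)
  K <- length(cfg$design$z_upper)
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    res <- lapply(seq_len(n_sims), function(j) {
      simulate_trial(cfg, sc, seed = trial_stream_seed(seed, i, j))
    })
    enrolled <- vapply(res, `[[`, numeric(1), "total_enrolled")
    rejected <- vapply(res, `[[`, logical(1), "rejected")
    stop_look <- vapply(res, `[[`, numeric(1), "stop_look")
    early <- vapply(res, function(r)
      r$outcome %in% c("stop_futility", "stop_efficacy"), logical(1))
    wk <- function(k) vapply(res, function(r) {
      if (nrow(r$per_look) >= k) r$per_look$w[k] else NA_real_
    }, numeric(1))
    ess_trial <- vapply(res, function(r) {
      e <- r$per_look$ess
      if (all(is.na(e))) NA_real_ else mean(e, na.rm = TRUE)
    }, numeric(1))
    w1 <- wk(1); w2 <- if (K >= 3) wk(2) else rep(NA_real_, n_sims)
    data.frame(
      scenario = sc$id, hypothesis = sc$hypothesis, congruent = sc$congruent,
      theta_c = sc$theta_c, theta_t = sc$theta_t,
      rejection_rate = mean(rejected),
      enrolled_mean = mean(enrolled),
      enrolled_q25 = iqr_lo(enrolled), enrolled_q75 = iqr_hi(enrolled),
      ess_mean = mean(ess_trial, na.rm = TRUE),
      ess_q25 = iqr_lo(ess_trial), ess_q75 = iqr_hi(ess_trial),
      pct_stop_1 = 100 * mean(early & stop_look == 1),
      pct_stop_2 = if (K >= 3) 100 * mean(early & stop_look == 2) else NA_real_,
      w1_mean = mean(w1, na.rm = TRUE),
      w1_q25 = iqr_lo(w1), w1_q75 = iqr_hi(w1),
      w2_mean = mean(w2, na.rm = TRUE),
      w2_q25 = iqr_lo(w2), w2_q75 = iqr_hi(w2),
      n_sims = n_sims)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sam_oc", "data.frame")
  out
}
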