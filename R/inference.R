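#' Conjugate update of a beta-mixture prior with binomial data
#'
#' Each component `(a_k, b_k)` becomes `(a_k + y, b_k + n - y)`; the
#' component weights are updated in proportion to the beta-binomial marginal
#' likelihood of the data under each component,
#' `m_k = C(n, y) B(a_k + y, b_k + n - y) / B(a_k, b_k)`, and renormalized.
#' Weight arithmetic is done in log space.
#'
#' @param prior a [beta_mixture()].
#' @param y observed events, `0 <= y <= n`.
#' @param n observed sample size; `n = 0` returns the prior unchanged.
#' @return The posterior [beta_mixture()].
#' @examples
#' update_mixture_posterior(beta_mixture(1, 1), 3, 10)  # Beta(4, 8)
#' @export
update_mixture_posterior <- function(prior, y, n) {
  stopifnot(inherits(prior, "beta_mixture"), n >= 0, y >= 0, y <= n)
  if (n == 0) return(prior)
  a <- prior$alpha + y
  b <- prior$beta + n - y
  log_m <- lbeta(a, b) - lbeta(prior$alpha, prior$beta)  # C(n,y) cancels
  lw <- log(prior$weights) + log_m
  lw <- lw - max(lw)
  beta_mixture(a, b, exp(lw) / sum(exp(lw)))
}

#' Posterior of one trial arm
#'
#' Bundles the conjugate posterior mixture of an arm's event rate with the
#' data it has absorbed.
#'
#' @param prior the arm's prior [beta_mixture()].
#' @param y,n cumulative events and observations absorbed.
#' @return A list of class `arm_posterior` with `mixture`, `n_obs`, `y_obs`.
#' @export
arm_posterior <- function(prior, y, n) {
  structure(list(mixture = update_mixture_posterior(prior, y, n),
                 n_obs = as.integer(n), y_obs = as.integer(y)),
            class = "arm_posterior")
}

as_mixture <- function(x) {
  if (inherits(x, "arm_posterior")) x$mixture
  else if (inherits(x, "beta_mixture")) x
  else stop("expected a beta_mixture or arm_posterior")
}

#' Posterior probability of noninferiority
#'
#' For the hypotheses `H0: theta_t - theta_c >= M` versus
#' `H1: theta_t - theta_c < M`, computes
#' `p = Pr(H1 | data) = integral F_t(theta_c + M) f_c(theta_c) d theta_c`,
#' where `f_c` is the control posterior density and `F_t` the test
#' posterior CDF (both beta mixtures, evaluated componentwise through the
#' regularized incomplete beta function). The one-dimensional integral is
#' done by adaptive quadrature; the argument of `F_t` is clamped to
#' `[0, 1]`.
#'
#' @param test,control [arm_posterior()] or [beta_mixture()] objects for
#'   the test and control rates.
#' @param margin_m noninferiority margin `M` on the risk-difference scale.
#' @param abs_tol absolute quadrature tolerance.
#' @return The probability `p` in `[0, 1]`.
#' @export
prob_noninferiority <- function(test, control, margin_m, abs_tol = 1e-6) {
  mt <- as_mixture(test)
  mc <- as_mixture(control)
  integrand <- function(th) dmix(mc, th) * pmix(mt, pmin(th + margin_m, 1))
  p <- stats::integrate(integrand, 0, 1, abs.tol = abs_tol,
                        rel.tol = 1e-8, subdivisions = 400L)$value
  min(max(p, 0), 1)
}

#' Interim/final decision from the posterior probability of noninferiority
#'
#' Applies the group-sequential Bayesian decision rule at analysis
#' `analysis_index`: at an interim, `p < C_futility` stops for futility and
#' `p > C_efficacy` stops for efficacy (strict inequalities; a value equal
#' to a threshold falls in the continuation region); at the final analysis
#' `p > C_efficacy` concludes noninferiority and anything else concludes
#' inferiority.
#'
#' @param p posterior probability of noninferiority.
#' @param design a [build_gs_design()] result.
#' @param analysis_index analysis number, `1 <= analysis_index <=`
#'   number of analyses.
#' @return A list of class `interim_decision` with `outcome` (one of
#'   `stop_futility`, `stop_efficacy`, `continue`, `final_noninferior`,
#'   `final_inferior`), `posterior_prob_h1` and `analysis_index`.
#' @export
interim_decision <- function(p, design, analysis_index) {
  stopifnot(inherits(design, "gs_design"), p >= 0, p <= 1)
  K <- length(design$z_upper)
  k <- as.integer(analysis_index)
  if (k < 1L || k > K)
    stop("'analysis_index' out of range 1..", K)
  outcome <- if (k == K) {
    if (p > design$prob_upper[K]) "final_noninferior" else "final_inferior"
  } else if (p < design$prob_lower[k]) {
    "stop_futility"
  } else if (p > design$prob_upper[k]) {
    "stop_efficacy"
  } else {
    "continue"
  }
  structure(list(outcome = outcome, posterior_prob_h1 = p,
                 analysis_index = k),
            class = "interim_decision")
}

#' @export
print.interim_decision <- function(x, ...) {
  cat(sprintf("analysis %d: Pr(H1 | data) = %.4f -> %s\n",
              x$analysis_index, x$posterior_prob_h1, x$outcome))
  invisible(x)
}
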