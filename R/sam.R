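#' Self-adapting mixture weight from congruence of current control data
#'
#' Likelihood-ratio odds of congruence between the current and historical
#' control rates. With current control data `y` events out of `n`, a
#' historical point estimate `theta_h_hat` and a congruence margin `delta`,
#' the odds are
#' `R = L(theta_h_hat) / max(L(theta_h_hat + delta), L(theta_h_hat - delta))`
#' with the binomial likelihood `L(p) = p^y (1-p)^(n-y)` (the binomial
#' coefficient cancels), and the mixture weight on the informative prior
#' component is `w = R / (1 + R)`. All likelihoods are evaluated in log
#' space, so no underflow is possible.
#'
#' With no data (`n = 0`) there is no evidence either way and `w = 0.5`.
#'
#' @param y current control events (non-negative integer, `y <= n`).
#' @param n current control patients observed.
#' @param theta_h_hat historical control rate point estimate in `(0, 1)`
#'   (the MAP-EM mixture mean, fixed at design time).
#' @param delta congruence margin: the clinically significant difference
#'   between historical and current control rates beyond which borrowing is
#'   inappropriate. Both `theta_h_hat - delta` and `theta_h_hat + delta`
#'   must lie inside `(0, 1)`.
#' @return The weight `w` in `[0, 1]`.
#' @examples
#' sam_weight(18, 100, 0.179, 0.02)
#' @export
sam_weight <- function(y, n, theta_h_hat, delta) {
  stopifnot(length(y) == 1, length(n) == 1, n >= 0, y >= 0, y <= n)
  if (delta <= 0) stop("'delta' must be positive")
  if (theta_h_hat - delta <= 0 || theta_h_hat + delta >= 1)
    stop("both likelihood evaluation points theta_h_hat +/- delta must lie in (0, 1)")
  if (n == 0) return(0.5)
  ll <- function(p) y * log(p) + (n - y) * log1p(-p)
  log_r <- ll(theta_h_hat) - max(ll(theta_h_hat + delta), ll(theta_h_hat - delta))
  # w = R/(1+R) = plogis(log R)
  stats::plogis(log_r)
}

#' Weakly informative prior component
#'
#' The robust (weakly informative) component of the SAM prior: a single
#' beta distribution centered at the historical estimate and carrying about
#' `ess_weak` patients of information. By default the shapes are
#' `Beta(theta_h_hat * ess_weak + 1, (1 - theta_h_hat) * ess_weak + 1)`
#' (the unit-information robust-MAP convention): the added `+1` keeps both
#' shapes above 1, so the prior density is bounded and its local-information
#' integral (hence [elir_ess()]) is finite. `unit_information = FALSE`
#' gives the plain mean-matched `Beta(theta_h_hat * ess_weak,
#' (1 - theta_h_hat) * ess_weak)`; note that with `ess_weak <= 1/min(theta,
#' 1-theta)` that form has a shape below 1 and an unbounded density at the
#' support boundary.
#'
#' @param theta_h_hat prior mean in `(0, 1)`.
#' @param ess_weak approximate information content in patients (positive).
#' @param unit_information add 1 to each shape (default `TRUE`).
#' @return A single-component [beta_mixture()].
#' @examples
#' weak_prior(0.179)                            # Beta(1.179, 1.821)
#' weak_prior(0.5, 2, unit_information = FALSE) # Beta(1, 1), uniform
#' @export
weak_prior <- function(theta_h_hat, ess_weak = 1, unit_information = TRUE) {
  stopifnot(theta_h_hat > 0, theta_h_hat < 1, ess_weak > 0)
  off <- if (unit_information) 1 else 0
  beta_mixture(theta_h_hat * ess_weak + off,
               (1 - theta_h_hat) * ess_weak + off, 1)
}

#' Assemble the SAM prior
#'
#' Self-Adapting Mixture prior for the control rate: the informative
#' (MAP-EM) mixture weighted by `w` plus the weakly informative component
#' weighted by `1 - w`. Component weights are rescaled accordingly,
#' renormalized, and components with weight below `1e-8` are dropped.
#'
#' @param w weight on the informative component, in `[0, 1]`
#'   (from [sam_weight()], or fixed).
#' @param informative the MAP-EM [beta_mixture()].
#' @param weak the weakly informative [beta_mixture()] (see [weak_prior()]).
#' @return A [beta_mixture()].
#' @export
build_sam_prior <- function(w, informative, weak) {
  stopifnot(w >= 0, w <= 1, inherits(informative, "beta_mixture"),
            inherits(weak, "beta_mixture"))
  alpha <- c(informative$alpha, weak$alpha)
  beta <- c(informative$beta, weak$beta)
  weights <- c(w * informative$weights, (1 - w) * weak$weights)
  keep <- weights >= 1e-8
  weights <- weights[keep] / sum(weights[keep])
  beta_mixture(alpha[keep], beta[keep], weights)
}
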