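#' Group-sequential design configuration
#'
#' Constants of the frequentist group-sequential scaffold for a
#' noninferiority comparison of two binomial rates (risk-difference margin,
#' 1:1 planned allocation).
#'
#' @param alpha one-sided type-I error level, in `(0, 0.5)`.
#' @param beta_err type-II error level, in `(0, 0.5)`.
#' @param margin_m noninferiority margin on the risk-difference scale
#'   (positive): largest tolerable excess event rate of the test arm.
#' @param theta_control assumed control event rate for sample sizing.
#' @param n_analyses number of analyses (interims plus final), at least 1.
#' @param info_fractions increasing information fractions in `(0, 1]`
#'   ending at 1; defaults to equally spaced.
#' @param gamma_alpha Hwang-Shih-DeCani parameter for the alpha-spending
#'   (efficacy, upper) bounds.
#' @param gamma_beta Hwang-Shih-DeCani parameter for the beta-spending
#'   (futility, lower) bounds.
#' @param binding logical; if `TRUE` (default) the futility bounds are
#'   honored in the alpha-spending recursion (binding futility). The
#'   default reproduces the worked cardiovascular-device example.
#' @param rate_digits round `theta_control` to this many digits in the
#'   one-stage sample-size formula (`NULL` to disable). Default 2.
#' @param grid_points nodes of the recursive-integration grid per analysis.
#' @return A list of class `design_config`.
#' @examples
#' cfg <- design_config()  # the motivating-example defaults
#' @export
design_config <- function(alpha = 0.05, beta_err = 0.2, margin_m = 0.04,
                          theta_control = 0.179, n_analyses = 3,
                          info_fractions = NULL, gamma_alpha = -4,
                          gamma_beta = -2, binding = TRUE,
                          rate_digits = 2, grid_points = 601) {
  stopifnot(alpha > 0, alpha < 0.5, beta_err > 0, beta_err < 0.5,
            theta_control > 0, theta_control < 1, n_analyses >= 1)
  if (margin_m <= 0) stop("'margin_m' must be positive")
  if (is.null(info_fractions))
    info_fractions <- seq_len(n_analyses) / n_analyses
  info_fractions <- as.numeric(info_fractions)
  if (length(info_fractions) != n_analyses ||
      any(diff(c(0, info_fractions)) <= 0) ||
      abs(info_fractions[n_analyses] - 1) > 1e-12)
    stop("'info_fractions' must be strictly increasing in (0, 1] and end at 1")
  structure(list(alpha = alpha, beta_err = beta_err, margin_m = margin_m,
                 theta_control = theta_control, n_analyses = as.integer(n_analyses),
                 info_fractions = info_fractions, gamma_alpha = gamma_alpha,
                 gamma_beta = gamma_beta, binding = isTRUE(binding),
                 rate_digits = rate_digits, grid_points = as.integer(grid_points)),
            class = "design_config")
}

#' Hwang-Shih-DeCani error-spending function
#'
#' Cumulative error spent at information fraction `t`:
#' `level * (1 - exp(-gamma * t)) / (1 - exp(-gamma))`, with the linear
#' limit `level * t` at `gamma = 0`.
#'
#' @param level total error to spend (e.g. `alpha` or `beta`).
#' @param gamma HSD shape parameter; negative values spend conservatively
#'   early.
#' @param t information fraction(s) in `[0, 1]`.
#' @return Cumulative spent error, vectorized over `t`.
#' @examples
#' hsd_spending(0.05, -4, 1 / 3)
#' @export
hsd_spending <- function(level, gamma, t) {
  if (any(t < 0 | t > 1)) stop("'t' must lie in [0, 1]")
  if (abs(gamma) < 1e-12) return(level * t)
  level * (1 - exp(-gamma * t)) / (1 - exp(-gamma))
}

#' One-stage (fixed) sample size for the noninferiority comparison
#'
#' Unpooled normal-approximation sample size for testing
#' `H0: theta_t - theta_c >= M` against `H1: theta_t - theta_c < M` at
#' `theta_t = theta_c`, 1:1 allocation: per arm
#' `n = (z_{1-alpha} + z_{1-beta})^2 * 2 * theta (1 - theta) / M^2`, rounded
#' up, with total `2n`. By default the control rate is first rounded to
#' `rate_digits` decimals (the convention of the worked example, where
#' 0.179 enters as 0.18 and the total is 2,282).
#'
#' @param cfg a [design_config()].
#' @return Total sample size over both arms (integer).
#' @examples
#' one_stage_sample_size(design_config())  # 2282
#' @export
one_stage_sample_size <- function(cfg) {
  stopifnot(inherits(cfg, "design_config"))
  th <- cfg$theta_control
  if (!is.null(cfg$rate_digits)) th <- round(th, cfg$rate_digits)
  z <- stats::qnorm(1 - cfg$alpha) + stats::qnorm(1 - cfg$beta_err)
  per_arm <- ceiling(z^2 * 2 * th * (1 - th) / cfg$margin_m^2)
  as.integer(2 * per_arm)
}

## ---- recursive numerical integration for sequential Z statistics ---------
# Internals work on the score scale W_k = Z_k * sqrt(t_k):
# increments W_k - W_{k-1} ~ N(zeta * (t_k - t_{k-1}), t_k - t_{k-1}),
# where zeta is the drift (E[Z] at t = 1). The continuing-path subdensity
# is propagated on a trapezoid grid.

trap_weights <- function(x) {
  n <- length(x)
  h <- diff(x)
  c(h[1] / 2, (h[-1] + h[-(n - 1)]) / 2, h[n - 1] / 2)
}

# P(W_k beyond 'thr' and no earlier stop), given continuing subdensity at k-1
gs_cross_prob <- function(dens, thr, zeta, dt, upper) {
  mu <- dens$w + zeta * dt
  sd <- sqrt(dt)
  qw <- trap_weights(dens$w)
  if (upper) sum(qw * dens$f * stats::pnorm((thr - mu) / sd, lower.tail = FALSE))
  else sum(qw * dens$f * stats::pnorm((thr - mu) / sd))
}

gs_advance <- function(dens, lo, hi, zeta, dt, n) {
  g <- seq(lo, hi, length.out = n)
  qw <- trap_weights(dens$w)
  f <- vapply(g, function(w)
    sum(qw * dens$f * stats::dnorm(w, dens$w + zeta * dt, sqrt(dt))),
    numeric(1))
  list(w = g, f = f)
}

gs_first_density <- function(lo, hi, zeta, t1, n) {
  g <- seq(lo, hi, length.out = n)
  list(w = g, f = stats::dnorm(g, zeta * t1, sqrt(t1)))
}

# Upper (efficacy) bounds spending increments a_inc under the null.
# zl = NULL -> non-binding (lower limit at mean - 9 SD); otherwise binding.
gs_upper_bounds <- function(t, a_inc, zl, n) {
  K <- length(t)
  zu <- numeric(K)
  dens <- NULL
  for (k in seq_len(K)) {
    tk <- t[k]
    lo_k <- if (is.null(zl)) -9 * sqrt(tk) else zl[k] * sqrt(tk)
    if (k == 1L) {
      zu[1] <- stats::qnorm(a_inc[1], lower.tail = FALSE)
    } else {
      dt <- t[k] - t[k - 1]
      f <- function(z) gs_cross_prob(dens, z * sqrt(tk), 0, dt, TRUE) - a_inc[k]
      zu[k] <- stats::uniroot(f, c(-4, 12), tol = 1e-9)$root
    }
    if (k < K) {
      dens_new <- if (k == 1L) gs_first_density(lo_k, zu[1] * sqrt(tk), 0, tk, n)
                  else gs_advance(dens, lo_k, zu[k] * sqrt(tk), 0, dt, n)
      dens <- dens_new
    }
  }
  zu
}

# Lower (futility) bounds from beta-spending increments b_inc at drift zeta,
# honoring the upper bounds; at the final look returns the leftover beta
# probability gap instead of a bound (used to solve the drift). During the
# drift search (strict = FALSE) an infeasible zeta -- one whose futility
# bound would cross the efficacy bound -- returns a positive sentinel gap
# (the drift is too small to spend the beta increment inside the
# continuation region); at the solved drift, strict = TRUE makes the
# crossing a user-facing error naming the offending look.
gs_lower_bounds <- function(t, b_inc, zu, zeta, n, strict = TRUE) {
  K <- length(t)
  zl <- numeric(K)
  dens <- NULL
  crossed <- function(k) {
    if (strict)
      stop("futility bound crosses efficacy bound at analysis ", k,
           "; relax the spending parameters")
    list(zl = NULL, gap = NA_real_)
  }
  for (k in seq_len(K)) {
    tk <- t[k]
    if (k == 1L) {
      zl[1] <- zeta * sqrt(tk) + stats::qnorm(b_inc[1])
    } else {
      dt <- t[k] - t[k - 1]
      if (k == K) {
        gap <- gs_cross_prob(dens, zu[K] * sqrt(tk), zeta, dt, FALSE) - b_inc[K]
        return(list(zl = c(zl[seq_len(K - 1)], zu[K]), gap = gap))
      }
      f <- function(z) gs_cross_prob(dens, z * sqrt(tk), zeta, dt, FALSE) - b_inc[k]
      if (f(zu[k]) < 0) return(crossed(k))
      zl[k] <- stats::uniroot(f, c(-12, zu[k]), tol = 1e-9)$root
    }
    if (zl[k] >= zu[k]) return(crossed(k))
    if (k < K) {
      dens_new <- if (k == 1L)
        gs_first_density(zl[1] * sqrt(tk), zu[1] * sqrt(tk), zeta, tk, n)
      else gs_advance(dens, zl[k] * sqrt(tk), zu[k] * sqrt(tk), zeta, dt, n)
      dens <- dens_new
    }
  }
  list(zl = zl, gap = NA_real_)  # K == 1 never reaches here
}

#' Build the group-sequential design
#'
#' Computes per-analysis efficacy (upper) and futility (lower) Z bounds for
#' Hwang-Shih-DeCani alpha- and beta-spending by the canonical recursive
#' numerical integration for sequential Z statistics (joint normal with
#' correlation `sqrt(t_i / t_j)` between analyses), the drift and
#' information inflation that make the two bounds meet at the final
#' analysis, the inflated maximum sample size, and the Bayesian
#' posterior-probability thresholds `Phi(Z)` of the decision rule.
#'
#' With `binding = TRUE` (default) the futility bounds are honored in the
#' alpha-spending recursion and the pair of bound sets is solved jointly by
#' fixed-point iteration; with `binding = FALSE` the upper bounds ignore
#' the futility bounds. Futility bounds are solved under the drifted design
#' alternative so that the cumulative beta spent equals `beta_err`.
#'
#' @param cfg a [design_config()].
#' @return An object of class `gs_design`: list with `z_lower`, `z_upper`,
#'   `prob_lower`, `prob_upper` (`Phi` of the bounds), `n_fixed`, `n_max`,
#'   `per_look_n` (cumulative planned enrollment, rounded up per look),
#'   `info_fractions`, `inflation`, `drift`, `alpha_spent`, `beta_spent`,
#'   and the `config`.
#' @examples
#' \donttest{
#' d <- build_gs_design(design_config())
#' round(d$z_upper, 2)  # 2.79 2.29 1.64
#' d$n_max              # 2386
#' }
#' @export
build_gs_design <- function(cfg) {
  stopifnot(inherits(cfg, "design_config"))
  t <- cfg$info_fractions
  K <- cfg$n_analyses
  n <- cfg$grid_points
  n_fixed <- one_stage_sample_size(cfg)
  z_fix <- stats::qnorm(1 - cfg$alpha) + stats::qnorm(1 - cfg$beta_err)

  if (K == 1L) {
    zu <- stats::qnorm(1 - cfg$alpha)
    des <- list(z_lower = zu, z_upper = zu, prob_lower = stats::pnorm(zu),
                prob_upper = stats::pnorm(zu), n_fixed = n_fixed,
                n_max = n_fixed, per_look_n = n_fixed, info_fractions = t,
                inflation = 1, drift = z_fix, alpha_spent = cfg$alpha,
                beta_spent = cfg$beta_err, config = cfg)
    return(structure(des, class = "gs_design"))
  }

  a_inc <- diff(c(0, hsd_spending(cfg$alpha, cfg$gamma_alpha, t)))
  b_inc <- diff(c(0, hsd_spending(cfg$beta_err, cfg$gamma_beta, t)))

  solve_lower <- function(zu) {
    # leftover-beta gap at the final look; NA where the beta increment
    # cannot be spent inside the continuation region (infeasible drift).
    # The gap decreases in the drift on the feasible interval; bracket the
    # root by an expanding search that respects feasibility, then polish.
    gap <- function(zeta) gs_lower_bounds(t, b_inc, zu, zeta, n, strict = FALSE)$gap
    lo <- z_fix
    g_lo <- gap(lo)
    while ((is.na(g_lo) || g_lo < 0) && lo > 0.3 * z_fix) {
      lo <- 0.97 * lo
      g_lo <- gap(lo)
    }
    if (is.na(g_lo) || g_lo < 0)
      stop("no feasible drift for the requested spending parameters")
    step <- 0.05 * z_fix
    z <- lo
    hi <- NA_real_
    repeat {
      z2 <- z + step
      g2 <- gap(z2)
      if (!is.na(g2) && g2 < 0) { hi <- z2; break }
      if (is.na(g2)) {
        step <- step / 2
        if (step < 1e-7)
          stop("no feasible drift for the requested spending parameters")
        next
      }
      z <- z2
    }
    zeta <- stats::uniroot(gap, c(z, hi), tol = 1e-9)$root
    list(zl = gs_lower_bounds(t, b_inc, zu, zeta, n, strict = TRUE)$zl,
         zeta = zeta)
  }

  zu <- gs_upper_bounds(t, a_inc, NULL, n)
  if (cfg$binding) {
    for (it in 1:60) {
      low <- solve_lower(zu)
      zu_new <- gs_upper_bounds(t, a_inc, low$zl, n)
      if (max(abs(zu_new - zu)) < 1e-8) { zu <- zu_new; break }
      zu <- zu_new
    }
  }
  low <- solve_lower(zu)
  zl <- low$zl
  zeta <- low$zeta
  inflation <- (zeta / z_fix)^2

  n_max <- as.integer(ceiling(n_fixed * inflation))
  if (n_max %% 2L == 1L) n_max <- n_max + 1L  # keep 1:1 total even
  per_look_n <- as.integer(ceiling(n_max * t))
  per_look_n[K] <- n_max

  structure(list(z_lower = zl, z_upper = zu,
                 prob_lower = stats::pnorm(zl), prob_upper = stats::pnorm(zu),
                 n_fixed = n_fixed, n_max = n_max, per_look_n = per_look_n,
                 info_fractions = t, inflation = inflation, drift = zeta,
                 alpha_spent = sum(a_inc), beta_spent = sum(b_inc),
                 config = cfg),
            class = "gs_design")
}

#' Map Z bounds to posterior-probability decision thresholds
#'
#' The Bayesian decision thresholds on the posterior probability of
#' noninferiority are the standard-normal CDF of the frequentist Z bounds,
#' `C = Phi(Z)`, elementwise.
#'
#' @param z_lower,z_upper numeric vectors of finite Z bounds.
#' @return A list with `prob_lower` and `prob_upper`.
#' @examples
#' z_to_probability_bounds(c(-0.42, 0.64, 1.64), c(2.79, 2.29, 1.64))
#' @export
z_to_probability_bounds <- function(z_lower, z_upper) {
  if (any(!is.finite(z_lower)) || any(!is.finite(z_upper)))
    stop("bounds must be finite")
  list(prob_lower = stats::pnorm(z_lower), prob_upper = stats::pnorm(z_upper))
}

#' @export
print.gs_design <- function(x, digits = 3, ...) {
  K <- length(x$z_upper)
  cat(sprintf("Group-sequential design: %d analyses, one-sided alpha %.3g, beta %.3g (%s futility)\n",
              K, x$config$alpha, x$config$beta_err,
              if (x$config$binding) "binding" else "non-binding"))
  cat(sprintf("One-stage n = %d, inflation %.4f, maximum n = %d\n",
              x$n_fixed, x$inflation, x$n_max))
  tab <- data.frame(
    analysis = seq_len(K),
    n_cum = x$per_look_n,
    z_futility = round(x$z_lower, 2),
    z_efficacy = round(x$z_upper, 2),
    futility = sprintf("Pr(H1) < %.*f", digits, x$prob_lower),
    continuation = sprintf("[%.*f, %.*f]", digits, x$prob_lower,
                           digits, x$prob_upper),
    efficacy = sprintf("Pr(H1) > %.*f", digits, x$prob_upper))
  tab$futility[K] <- "--"
  tab$continuation[K] <- "--"
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a group-sequential design to JSON
#'
#' @param design a [build_gs_design()] result.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The path (invisibly) or a JSON string.
#' @export
gs_design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "gs_design"))
  keep <- c("z_lower", "z_upper", "prob_lower", "prob_upper", "n_fixed",
            "n_max", "per_look_n", "info_fractions", "inflation", "drift")
  txt <- jsonlite::toJSON(design[keep], auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}
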