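#' Aggregated historical control studies
#'
#' One row per historical study of the control device/treatment, holding the
#' arm size and the number of primary-endpoint events. These summary counts
#' are all the historical information the MAP prior machinery needs.
#'
#' @param n_patients positive integer vector of arm sizes.
#' @param n_events non-negative integer vector of event counts,
#'   `n_events <= n_patients` elementwise.
#' @param study_id optional identifiers; defaults to `S1, S2, ...`.
#' @return A `data.frame` of class `historical_studies` with columns
#'   `study_id`, `n_patients`, `n_events`.
#' @examples
#' historical_studies(c(204, 220, 499, 60), c(30, 20, 14, 10))
#' @export
historical_studies <- function(n_patients, n_events, study_id = NULL) {
  n_patients <- as.integer(n_patients)
  n_events <- as.integer(n_events)
  if (length(n_patients) < 1L || length(n_patients) != length(n_events))
    stop("'n_patients' and 'n_events' must be non-empty and of equal length")
  if (any(n_patients <= 0L)) stop("'n_patients' must be positive")
  if (any(n_events < 0L) || any(n_events > n_patients))
    stop("'n_events' must satisfy 0 <= n_events <= n_patients")
  if (is.null(study_id)) study_id <- paste0("S", seq_along(n_patients))
  structure(data.frame(study_id = as.character(study_id),
                       n_patients = n_patients, n_events = n_events,
                       stringsAsFactors = FALSE),
            class = c("historical_studies", "data.frame"))
}

#' Read historical studies from CSV
#'
#' Expects a UTF-8, comma-separated file with header
#' `study_id,n_patients,n_events`.
#'
#' @param path file path.
#' @return A [historical_studies()] object.
#' @export
read_historical_studies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("study_id", "n_patients", "n_events")
  if (!all(need %in% names(df)))
    stop("historical CSV must have columns: ", paste(need, collapse = ", "))
  historical_studies(df$n_patients, df$n_events, df$study_id)
}

#' Between-study heterogeneity (Cochran's Q and I-squared)
#'
#' Computes Cochran's Q with inverse-variance fixed-effect weights on the
#' chosen effect scale and Higgins' I-squared, `I2 = max(0, (Q - df)/Q)`.
#' Effect sizes and sampling variances come from [metafor::escalc()]
#' (`measure = "PLO"` for logit proportions, `"PR"` for raw proportions),
#' which applies the standard 0.5 continuity correction to zero cells on the
#' logit scale; when a correction was needed the result carries
#' `continuity_corrected = TRUE`.
#'
#' @param studies a [historical_studies()] object (or coercible data.frame)
#'   with at least two studies.
#' @param scale `"logit"` (default) or `"raw"` proportion scale.
#' @return A list of class `heterogeneity` with `q_statistic`, `df`,
#'   `i_squared`, `p_value`, `scale`, `continuity_corrected`.
#' @examples
#' h <- historical_studies(c(204, 220, 499, 60), c(30, 20, 14, 10))
#' heterogeneity_i2(h)
#' @export
heterogeneity_i2 <- function(studies, scale = c("logit", "raw")) {
  scale <- match.arg(scale)
  if (nrow(studies) < 2L)
    stop("heterogeneity requires at least 2 studies")
  zero_cell <- studies$n_events == 0L | studies$n_events == studies$n_patients
  if (scale == "logit") {
    es <- metafor::escalc(measure = "PLO", xi = studies$n_events,
                          ni = studies$n_patients, add = 1 / 2, to = "only0")
  } else {
    es <- metafor::escalc(measure = "PR", xi = studies$n_events,
                          ni = studies$n_patients, add = 1 / 2, to = "only0")
  }
  yi <- as.numeric(es$yi)
  vi <- as.numeric(es$vi)
  if (any(!is.finite(yi)) || any(!is.finite(vi)) || any(vi <= 0))
    stop("non-finite effect size or variance; check the study counts")
  wi <- 1 / vi
  ybar <- sum(wi * yi) / sum(wi)
  q <- sum(wi * (yi - ybar)^2)
  df <- nrow(studies) - 1L
  structure(list(q_statistic = q, df = df,
                 i_squared = max(0, (q - df) / q),
                 p_value = stats::pchisq(q, df, lower.tail = FALSE),
                 scale = scale,
                 continuity_corrected = scale == "logit" && any(zero_cell)),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (df = %d, p = %.4g), I^2 = %.1f%% [%s scale]%s\n",
              x$q_statistic, x$df, x$p_value, 100 * x$i_squared, x$scale,
              if (x$continuity_corrected) " (0.5 continuity correction)" else ""))
  invisible(x)
}

#' MCMC control settings for the MAP hierarchical model
#'
#' @param n_chains number of parallel chains (at least 2 for split-Rhat).
#' @param n_adapt adaptation ("tuning") iterations per chain.
#' @param n_iter retained sampling iterations per chain.
#' @param mu_mean,mu_sd Normal prior for the population logit rate mu.
#' @param tau_scale Half-Normal scale for the between-study SD tau.
#' @param max_tuning_rounds extra rounds with doubled adaptation/iterations
#'   attempted before declaring non-convergence.
#' @return A list of settings for [fit_map_hierarchical()].
#' @export
map_mcmc_control <- function(n_chains = 4, n_adapt = 2000, n_iter = 2500,
                             mu_mean = 0, mu_sd = 2, tau_scale = 1,
                             max_tuning_rounds = 2) {
  stopifnot(n_chains >= 2, n_adapt >= 100, n_iter >= 500)
  list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
       n_iter = as.integer(n_iter), mu_mean = mu_mean, mu_sd = mu_sd,
       tau_scale = tau_scale, max_tuning_rounds = as.integer(max_tuning_rounds))
}

map_jags_model <- "
model {
  for (j in 1:J) {
    y[j] ~ dbin(theta[j], n[j])
    logit(theta[j]) <- mu + tau * z[j]
    z[j] ~ dnorm(0, 1)
  }
  mu ~ dnorm(mu_mean, pow(mu_sd, -2))
  tau ~ dnorm(0, pow(tau_scale, -2)) T(0,)
  z_new ~ dnorm(0, 1)
  theta_pred <- ilogit(mu + tau * z_new)
}
"

# split-Rhat (rank-free version): split each chain in half, then the usual
# between/within variance ratio over the 2*n_chains half-chains.
split_rhat <- function(draws_by_chain) {
  halves <- do.call(cbind, lapply(draws_by_chain, function(x) {
    m <- length(x) %/% 2L
    cbind(x[seq_len(m)], x[m + seq_len(m)])
  }))
  n <- nrow(halves)
  mu_j <- colMeans(halves)
  s2_j <- apply(halves, 2, stats::var)
  w <- mean(s2_j)
  b <- n * stats::var(mu_j)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Fit the MAP hierarchical model to historical studies
#'
#' Meta-analytic-predictive (MAP) prior elicitation: events are binomial
#' within each historical study, study-level logit rates are exchangeable
#' Normal(mu, tau^2), with a weak Normal prior on mu and a Half-Normal prior
#' on tau. The returned draws are from the predictive distribution of the
#' control rate in a new exchangeable trial,
#' `inverse-logit(mu + tau * z), z ~ N(0, 1)` -- the MAP prior for the
#' historical control rate. Sampling is by MCMC (JAGS via \pkg{rjags}),
#' with split-Rhat convergence diagnostics on `mu` and `tau`; if any
#' split-Rhat is at or above 1.01 the fit is retried with doubled tuning,
#' and a persistent failure is an error carrying the diagnostics.
#'
#' @param studies a [historical_studies()] object; one study is allowed (the
#'   priors regularize).
#' @param mcmc settings from [map_mcmc_control()].
#' @param seed integer seed; chain `i` is initialized with RNG seed
#'   `seed + i`.
#' @return An object of class `map_posterior`: list with `draws` (pooled
#'   predictive draws of the control rate, strictly inside (0,1)),
#'   `draws_by_chain`, `n_chains`, and `diagnostics` (split-Rhat and
#'   effective draws for `mu`, `tau`, `theta_pred`).
#' @examples
#' \donttest{
#' h <- historical_studies(c(204, 220, 499, 60), c(30, 20, 14, 10))
#' fit <- fit_map_hierarchical(h, map_mcmc_control(n_adapt = 500, n_iter = 1000))
#' mean(fit$draws)
#' }
#' @export
fit_map_hierarchical <- function(studies, mcmc = map_mcmc_control(), seed = 1) {
  stopifnot(nrow(studies) >= 1L)
  dat <- list(J = nrow(studies), y = studies$n_events, n = studies$n_patients,
              mu_mean = mcmc$mu_mean, mu_sd = mcmc$mu_sd,
              tau_scale = mcmc$tau_scale)
  run <- function(n_adapt, n_iter) {
    inits <- lapply(seq_len(mcmc$n_chains), function(i) {
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = as.integer((seed + i) %% .Machine$integer.max))
    })
    jm <- rjags::jags.model(textConnection(map_jags_model), data = dat,
                            inits = inits, n.chains = mcmc$n_chains,
                            n.adapt = n_adapt, quiet = TRUE)
    samp <- rjags::coda.samples(jm, c("mu", "tau", "theta_pred"),
                                n.iter = n_iter, progress.bar = "none")
    samp
  }
  n_adapt <- mcmc$n_adapt
  n_iter <- mcmc$n_iter
  for (round in 0:mcmc$max_tuning_rounds) {
    samp <- run(n_adapt, n_iter)
    by_chain <- function(par) lapply(samp, function(ch) as.numeric(ch[, par]))
    rhat <- vapply(c("mu", "tau", "theta_pred"),
                   function(p) split_rhat(by_chain(p)), numeric(1))
    if (max(rhat[c("mu", "tau")]) < 1.01) break
    n_adapt <- 2L * n_adapt
    n_iter <- 2L * n_iter
  }
  n_eff <- vapply(c("mu", "tau", "theta_pred"), function(p) {
    sum(coda::effectiveSize(samp[, p]))
  }, numeric(1))
  diagnostics <- data.frame(parameter = c("mu", "tau", "theta_pred"),
                            split_rhat = unname(rhat), n_eff = unname(n_eff))
  if (max(rhat[c("mu", "tau")]) >= 1.01) {
    stop("MAP hierarchical MCMC did not converge (split-Rhat >= 1.01):\n",
         paste(utils::capture.output(print(diagnostics)), collapse = "\n"))
  }
  draws_by_chain <- lapply(samp, function(ch) as.numeric(ch[, "theta_pred"]))
  draws <- unlist(draws_by_chain, use.names = FALSE)
  draws <- pmin(pmax(draws, .Machine$double.eps), 1 - .Machine$double.eps)
  structure(list(draws = draws, draws_by_chain = draws_by_chain,
                 n_chains = mcmc$n_chains, diagnostics = diagnostics),
            class = "map_posterior")
}

#' @export
print.map_posterior <- function(x, ...) {
  cat(sprintf("MAP predictive posterior: %d draws over %d chains, mean %.3f\n",
              length(x$draws), x$n_chains, mean(x$draws)))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

## ---- EM fit of a beta mixture to posterior draws -------------------------

# weighted ML fit of a single beta component; par on log scale, analytic
# gradient from digamma
fit_beta_weighted <- function(x, r, a0, b0) {
  sw <- sum(r)
  s_lx <- sum(r * log(x))
  s_l1x <- sum(r * log1p(-x))
  nll <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    -((a - 1) * s_lx + (b - 1) * s_l1x - sw * lbeta(a, b))
  }
  grad <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    dab <- digamma(a + b)
    ga <- s_lx - sw * (digamma(a) - dab)
    gb <- s_l1x - sw * (digamma(b) - dab)
    -c(ga * a, gb * b)  # chain rule through log scale
  }
  fit <- stats::optim(log(c(a0, b0)), nll, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  exp(fit$par)
}

beta_mix_loglik <- function(x, alpha, beta, weights) {
  lp <- vapply(seq_along(alpha), function(k) {
    log(weights[k]) + stats::dbeta(x, alpha[k], beta[k], log = TRUE)
  }, numeric(length(x)))
  m <- apply(lp, 1, max)
  sum(m + log(rowSums(exp(lp - m))))
}

em_fit_once <- function(x, k, seed, tol, max_iter) {
  set.seed(seed)
  # initialization: method of moments on a k-means split of the draws
  if (k == 1L) {
    cl <- rep(1L, length(x))
  } else {
    cl <- stats::kmeans(x, centers = k, nstart = 5)$cluster
  }
  alpha <- beta <- weights <- numeric(k)
  for (j in seq_len(k)) {
    xj <- x[cl == j]
    m <- mean(xj)
    v <- max(stats::var(xj), 1e-8)
    common <- max(m * (1 - m) / v - 1, 0.1)
    alpha[j] <- m * common
    beta[j] <- (1 - m) * common
    weights[j] <- length(xj) / length(x)
  }
  ll <- beta_mix_loglik(x, alpha, beta, weights)
  ll_trace <- ll
  for (it in seq_len(max_iter)) {
    # E step: responsibilities in log space
    lp <- vapply(seq_len(k), function(j) {
      log(weights[j]) + stats::dbeta(x, alpha[j], beta[j], log = TRUE)
    }, numeric(length(x)))
    mrow <- apply(lp, 1, max)
    resp <- exp(lp - mrow)
    resp <- resp / rowSums(resp)
    # M step
    weights <- colMeans(resp)
    if (any(weights < 1e-4)) {
      return(list(degenerate = TRUE, k = k))
    }
    for (j in seq_len(k)) {
      ab <- fit_beta_weighted(x, resp[, j], alpha[j], beta[j])
      if (any(!is.finite(ab)) || any(ab > 1e8))
        return(list(degenerate = TRUE, k = k))
      alpha[j] <- ab[1]; beta[j] <- ab[2]
    }
    ll_new <- beta_mix_loglik(x, alpha, beta, weights)
    ll_trace <- c(ll_trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) { ll <- ll_new; break }
    ll <- ll_new
  }
  ord <- order(weights, decreasing = TRUE)
  list(degenerate = FALSE,
       mix = beta_mixture(alpha[ord], beta[ord], weights[ord]),
       loglik = ll, loglik_trace = ll_trace, n_iter = length(ll_trace) - 1L)
}

#' Approximate posterior draws by a beta mixture (EM)
#'
#' Maximum-likelihood fit of a k-component beta mixture to MCMC draws, by
#' expectation-maximization: responsibilities in the E step, weighted
#' maximum-likelihood beta fits (BFGS with analytic digamma gradients) in
#' the M step. Initialization is method-of-moments on a k-means split of the
#' draws under a fixed seed. The EM log-likelihood is monotone
#' non-decreasing across iterations and the trace is kept on the result. A
#' degenerate component (weight below 1e-4, or parameter overflow) causes a
#' refit with one component fewer, with a warning.
#'
#' @param samples a [fit_map_hierarchical()] result or a numeric vector of
#'   at least 1000 draws in `(0, 1)`.
#' @param n_components number of beta components, or `"auto"` to select
#'   among 1--4 by AIC.
#' @param seed integer seed for the k-means initialization.
#' @param tol relative convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap.
#' @return A [beta_mixture()] (components ordered by descending weight) with
#'   attributes `loglik`, `loglik_trace`, `n_iter`.
#' @export
fit_beta_mixture_em <- function(samples, n_components = 2, seed = 1,
                                tol = 1e-8, max_iter = 500) {
  x <- if (inherits(samples, "map_posterior")) samples$draws else as.numeric(samples)
  if (length(x) < 1000L)
    stop("at least 1000 draws are required for a stable EM fit")
  if (any(x <= 0 | x >= 1)) stop("draws must lie strictly inside (0, 1)")
  if (identical(n_components, "auto")) {
    fits <- lapply(1:4, function(k) {
      tryCatch(suppressWarnings(fit_beta_mixture_em(x, k, seed, tol, max_iter)),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    aic <- vapply(fits, function(f) {
      k <- length(f$alpha)
      2 * (3 * k - 1) - 2 * attr(f, "loglik")
    }, numeric(1))
    return(fits[[which.min(aic)]])
  }
  k <- as.integer(n_components)
  stopifnot(k >= 1L)
  while (k >= 1L) {
    fit <- em_fit_once(x, k, seed, tol, max_iter)
    if (!fit$degenerate) {
      mix <- fit$mix
      attr(mix, "loglik") <- fit$loglik
      attr(mix, "loglik_trace") <- fit$loglik_trace
      attr(mix, "n_iter") <- fit$n_iter
      return(mix)
    }
    warning("degenerate component with ", k,
            " components; refitting with ", k - 1L)
    k <- k - 1L
  }
  stop("EM failed for all component counts")
}
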