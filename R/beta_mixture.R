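#' Weighted mixture of beta distributions
#'
#' The universal prior/posterior container of the package: every prior
#' (MAP-EM, weak, SAM) and every conjugate posterior for an event rate is a
#' weighted mixture of beta densities.
#'
#' @param alpha numeric vector of positive first shape parameters, one per
#'   component.
#' @param beta numeric vector of positive second shape parameters, same
#'   length as `alpha`.
#' @param weights numeric vector of component weights in `[0, 1]`. Must sum
#'   to 1 within `1e-6`; they are renormalized to sum to 1 exactly. Defaults
#'   to equal weights.
#' @return An object of class `beta_mixture`: a list with elements `alpha`,
#'   `beta` and `weights`.
#' @examples
#' m <- beta_mixture(c(10.59, 4.53), c(54.71, 17.92), c(0.58, 0.42))
#' mixture_mean(m)
#' @export
beta_mixture <- function(alpha, beta, weights = NULL) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  if (length(alpha) < 1L || length(alpha) != length(beta))
    stop("'alpha' and 'beta' must be non-empty vectors of equal length")
  if (any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(alpha <= 0) || any(beta <= 0))
    stop("all shape parameters must be finite and strictly positive")
  if (is.null(weights)) weights <- rep(1 / length(alpha), length(alpha))
  weights <- as.numeric(weights)
  if (length(weights) != length(alpha))
    stop("'weights' must match the number of components")
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1))
    stop("'weights' must lie in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("'weights' must sum to 1 (got ", format(sum(weights)), ")")
  structure(list(alpha = alpha, beta = beta, weights = weights / sum(weights)),
            class = "beta_mixture")
}

#' @export
print.beta_mixture <- function(x, digits = 4, ...) {
  cat("Beta mixture with", length(x$alpha), "component(s)\n")
  tab <- data.frame(weight = round(x$weights, digits),
                    alpha = round(x$alpha, digits),
                    beta = round(x$beta, digits),
                    mean = round(x$alpha / (x$alpha + x$beta), digits))
  print(tab, row.names = FALSE)
  cat("mixture mean:", round(mixture_mean(x), digits), "\n")
  invisible(x)
}

n_components <- function(mix) length(mix$alpha)

#' Mixture density, distribution, quantile and random generation
#'
#' Component-wise evaluation of the beta-mixture density and CDF, quantiles
#' by bisection on the CDF, and random draws by component sampling.
#'
#' @param mix a [beta_mixture()].
#' @param x,q numeric vector of evaluation points in `[0, 1]`.
#' @param p numeric vector of probabilities in `(0, 1)`.
#' @param n number of draws.
#' @param log logical; return the log density.
#' @param tol bisection tolerance on the quantile scale.
#' @return `dmix`/`pmix` a numeric vector; `qmix` quantiles; `rmix` draws in
#'   `(0, 1)`.
#' @export
dmix <- function(mix, x, log = FALSE) {
  stopifnot(inherits(mix, "beta_mixture"))
  d <- vapply(seq_along(x), function(i) {
    sum(mix$weights * stats::dbeta(x[i], mix$alpha, mix$beta))
  }, numeric(1))
  if (log) base::log(d) else d
}

#' @rdname dmix
#' @export
pmix <- function(mix, q) {
  stopifnot(inherits(mix, "beta_mixture"))
  vapply(seq_along(q), function(i) {
    sum(mix$weights * stats::pbeta(q[i], mix$alpha, mix$beta))
  }, numeric(1))
}

#' @rdname dmix
#' @export
qmix <- function(mix, p, tol = 1e-8) {
  stopifnot(inherits(mix, "beta_mixture"))
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly inside (0, 1)")
  vapply(p, function(pp) {
    lo <- 0; hi <- 1
    # plain bisection: pmix is monotone and continuous on [0, 1]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (pmix(mix, mid) < pp) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' @rdname dmix
#' @export
rmix <- function(mix, n) {
  stopifnot(inherits(mix, "beta_mixture"))
  k <- sample.int(n_components(mix), n, replace = TRUE, prob = mix$weights)
  stats::rbeta(n, mix$alpha[k], mix$beta[k])
}

#' Mixture mean
#'
#' @param mix a [beta_mixture()].
#' @return The weighted average of component means.
#' @export
mixture_mean <- function(mix) {
  stopifnot(inherits(mix, "beta_mixture"))
  sum(mix$weights * mix$alpha / (mix$alpha + mix$beta))
}

#' Summarize a beta mixture
#'
#' Mean and quantiles of a beta-mixture distribution; the quantiles invert
#' the mixture CDF by bisection.
#'
#' @param mix a [beta_mixture()].
#' @param probs quantile levels in `(0, 1)`.
#' @return A list with `mean` and a named vector `quantiles`.
#' @examples
#' m <- beta_mixture(c(10.59, 4.53), c(54.71, 17.92), c(0.58, 0.42))
#' mixture_summary(m)
#' @export
mixture_summary <- function(mix, probs = c(0.025, 0.5, 0.975)) {
  q <- qmix(mix, probs)
  names(q) <- paste0(format(100 * probs, trim = TRUE), "%")
  list(mean = mixture_mean(mix), quantiles = q)
}

#' Serialize a beta mixture to and from JSON
#'
#' The interchange format is
#' `{"components":[{"alpha":..,"beta":..},...],"weights":[..]}`.
#'
#' @param mix a [beta_mixture()].
#' @param path optional file path; when `NULL`, `mixture_to_json` returns the
#'   JSON string.
#' @param x a JSON string, a file path, or an already-parsed list.
#' @return `mixture_to_json`: the path (invisibly) or a JSON string;
#'   `mixture_from_json`: a `beta_mixture`.
#' @export
mixture_to_json <- function(mix, path = NULL) {
  stopifnot(inherits(mix, "beta_mixture"))
  obj <- list(components = lapply(seq_along(mix$alpha), function(k) {
    list(alpha = mix$alpha[k], beta = mix$beta[k])
  }), weights = mix$weights)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname mixture_to_json
#' @export
mixture_from_json <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  comp <- x$components
  beta_mixture(vapply(comp, `[[`, numeric(1), "alpha"),
               vapply(comp, `[[`, numeric(1), "beta"),
               unlist(x$weights))
}
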