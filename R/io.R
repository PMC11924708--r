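#' Load and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration, rejects
#' unknown keys, fills documented defaults, and returns a validated list.
#' Recognized keys: `historical_csv`, `map_em` (path to a mixture JSON or
#' an inline `{components, weights}` object), `theta_h_hat`, `alpha`,
#' `beta_err`, `margin_m`, `delta`, `theta_control`, `n_analyses`,
#' `info_fractions`, `gamma_alpha`, `gamma_beta`, `binding`, `ess_weak`,
#' `weight_mode`, `fixed_weight`, `n_sims`, `seed`.
#'
#' @param path configuration file path.
#' @return A list of class `samgsd_config` with defaults filled. Mixture
#'   objects are parsed into [beta_mixture()]s.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yml = , yaml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = FALSE),
                stop("unsupported config extension: .", ext))
  defaults <- list(historical_csv = NULL, map_em = NULL, theta_h_hat = NULL,
                   alpha = 0.05, beta_err = 0.2, margin_m = 0.04,
                   delta = 0.02, theta_control = 0.18, n_analyses = 3,
                   info_fractions = NULL, gamma_alpha = -4, gamma_beta = -2,
                   binding = TRUE, ess_weak = 1, weight_mode = "adaptive",
                   fixed_weight = 0.5, n_sims = 1000, seed = 1)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  if (!is.null(cfg$map_em)) {
    cfg$map_em <- if (is.character(cfg$map_em)) mixture_from_json(cfg$map_em)
                  else mixture_from_json(cfg$map_em)
  }
  if (!cfg$weight_mode %in% c("adaptive", "fixed"))
    stop("'weight_mode' must be 'adaptive' or 'fixed'")
  for (key in c("alpha", "beta_err", "margin_m", "delta", "theta_control")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("configuration key '", key, "' must be a positive number")
  }
  structure(cfg, class = "samgsd_config")
}

#' Design configuration from a run configuration
#'
#' @param cfg a [load_config()] result.
#' @return A [design_config()].
#' @export
config_to_design <- function(cfg) {
  design_config(alpha = cfg$alpha, beta_err = cfg$beta_err,
                margin_m = cfg$margin_m, theta_control = cfg$theta_control,
                n_analyses = cfg$n_analyses,
                info_fractions = cfg$info_fractions,
                gamma_alpha = cfg$gamma_alpha, gamma_beta = cfg$gamma_beta,
                binding = cfg$binding)
}

# stable djb2-style rolling hash over UTF-8 bytes, reported as 8 hex digits
config_hash <- function(obj) {
  txt <- as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                       force = TRUE))
  bytes <- as.integer(charToRaw(enc2utf8(txt)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the resolved configuration hash, the seed, the package version
#' and a UTC timestamp. Written before any results so a run can always be
#' tied back to its inputs.
#'
#' @param config the resolved configuration (any serializable list).
#' @param seed integer seed of the run.
#' @param path output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(config, seed, path) {
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   version = as.character(utils::packageVersion("samgsd")),
                   created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                        tz = "UTC"))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE)), path)
  invisible(manifest)
}

#' Write fixture files for the worked example
#'
#' Writes, under `dir`: the four historical control studies
#' (`historical_studies.csv`), the published two-component MAP-EM mixture
#' (`map_em_mixture.json`), the eight-scenario grid for
#' `theta_h = 0.179, delta = 0.02, m = 0.04` (`scenarios.csv`), and a small
#' file of synthetic draws from that mixture (`map_mcmc_draws.csv`,
#' seeded). Regeneration with the same seed is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the synthetic draws.
#' @param n_draws number of synthetic draws.
#' @return Character vector of the written paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1, n_draws = 2000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("historical_studies.csv", "map_em_mixture.json",
                            "scenarios.csv", "map_mcmc_draws.csv"))
  hist <- historical_studies(c(204, 220, 499, 60), c(30, 20, 14, 10))
  utils::write.csv(hist, paths[1], row.names = FALSE, quote = FALSE)
  mix <- beta_mixture(c(10.59, 4.53), c(54.71, 17.92), c(0.58, 0.42))
  mixture_to_json(mix, paths[2])
  utils::write.csv(default_scenarios(0.179, 0.02, 0.04), paths[3],
                   row.names = FALSE, quote = FALSE)
  set.seed(seed)
  draws <- data.frame(draw = round(rmix(mix, n_draws), 8))
  utils::write.csv(draws, paths[4], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write operating characteristics as CSV
#'
#' Probabilities and rates are rounded to 3 decimals; enrollment and ESS
#' summaries to 1 decimal.
#'
#' @param oc a [run_scenarios()] result.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_oc_csv <- function(oc, path) {
  out <- as.data.frame(oc)
  p3 <- c("rejection_rate", "w1_mean", "w1_q25", "w1_q75",
          "w2_mean", "w2_q25", "w2_q75")
  d1 <- c("enrolled_mean", "enrolled_q25", "enrolled_q75",
          "ess_mean", "ess_q25", "ess_q75", "pct_stop_1", "pct_stop_2")
  out[p3] <- lapply(out[p3], round, 3)
  out[d1] <- lapply(out[d1], round, 1)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
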