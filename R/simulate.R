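detection_intercept <- function(scenario) {
  switch(scenario,
         low = qlogis(0.13),
         high = qlogis(0.84),
         stop("detection scenario must be 'low' or 'high'"))
}

trend_coefficients <- function(trend, n_abundance_terms = 1) {
  switch(trend,
         none = NULL,
         weak = c(0, rep(0.1, n_abundance_terms), 0.05),
         strong = c(0, rep(0.1, n_abundance_terms), 0.25),
         stop("trend must be 'none', 'weak' or 'strong'"))
}

#' Configure a simulation scenario
#'
#' A full generative description of one survey scenario: site-level forest
#' cover (Uniform(0,1), centered) drives expected abundance through a log
#' link with intercept `log(5)` and a per-dataset slope drawn as
#' `(random sign) * Uniform(0.5, 1.5)`; a visit-level wind covariate
#' (standard normal) enters detection on the logit scale with slope 0.4
#' around an intercept of `logit(0.13)` (low) or `logit(0.84)` (high). For
#' multi-season scenarios abundance follows the multiplicative growth
#' recursion with `delta = (0, 0.1, 0.05)` (weak trend) or `(0, 0.1, 0.25)`
#' (strong trend) over the intercept, forest and season-index terms.
#'
#' @param n_sites number of surveyed sites.
#' @param n_visits independent visits per site per season.
#' @param n_seasons 1 for single-season; >= 2 with a `trend` for
#'   multi-season.
#' @param detection `"low"` (mean detection 0.13) or `"high"` (0.84).
#' @param trend `"none"`, `"weak"` or `"strong"` seasonal growth trend.
#' @param seed base seed; replicate r of a benchmark uses `seed + r`.
#' @param n_replicates replicate count tag used by the benchmark.
#' @param beta0,beta1_range,alpha1 generating constants, exposed for
#'   sensitivity analyses; defaults are the package's study conditions.
#' @return a list of class `nmix_scenario`.
#' @export
scenario_config <- function(n_sites = 50, n_visits = 4, n_seasons = 1,
                            detection = c("high", "low"),
                            trend = c("none", "weak", "strong"),
                            seed = 1, n_replicates = 100,
                            beta0 = log(5), beta1_range = c(0.5, 1.5),
                            alpha1 = 0.4) {
  detection <- match.arg(detection)
  trend <- match.arg(trend)
  if (n_seasons > 1 && trend == "none")
    stop("multi-season scenarios require a 'weak' or 'strong' trend")
  if (n_seasons == 1 && trend != "none")
    stop("a trend requires n_seasons >= 2")
  structure(list(n_sites = as.integer(n_sites),
                 n_visits = as.integer(n_visits),
                 n_seasons = as.integer(n_seasons),
                 detection = detection, trend = trend,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 beta0 = beta0, beta1_range = beta1_range,
                 alpha0 = detection_intercept(detection), alpha1 = alpha1,
                 delta = trend_coefficients(trend)),
            class = "nmix_scenario")
}

#' @export
print.nmix_scenario <- function(x, ...) {
  cat(sprintf(
    "scenario: %d sites x %d visits x %d season(s), %s detection%s, seed %d\n",
    x$n_sites, x$n_visits, x$n_seasons, x$detection,
    if (x$trend != "none") paste0(", ", x$trend, " trend") else "", x$seed))
  invisible(x)
}

scenario_label <- function(cfg) {
  paste0(if (cfg$n_seasons > 1) paste0(cfg$trend, "_trend_") else "single_",
         cfg$detection, "_", cfg$n_sites, "sites",
         if (cfg$n_visits != 4) paste0("_", cfg$n_visits, "visits") else "")
}

simulate_scenario <- function(config, seed) {
  stopifnot(inherits(config, "nmix_scenario"))
  if (!is.null(seed)) set.seed(seed)
  S <- config$n_sites; J <- config$n_visits; Tn <- config$n_seasons

  forest <- runif(S)
  forest <- forest - mean(forest)
  beta1 <- sample(c(-1, 1), 1) * runif(1, config$beta1_range[1],
                                       config$beta1_range[2])
  beta <- c(config$beta0, beta1)
  alpha <- c(config$alpha0, config$alpha1)
  delta <- config$delta

  spec <- model_spec(abundance = "forest", detection = "wind",
                     seasonal = Tn > 1)
  shell <- nmix_data(array(0L, dim = c(S, J, Tn)),
                     site_covariates = cbind(forest = forest),
                     visit_covariates = list(wind = array(0, c(S, J, Tn))))
  mu <- multiseason_expected_abundance(beta, delta, shell, spec)

  N <- matrix(0L, S, Tn)
  for (t in seq_len(Tn)) N[, t] <- rpois(S, mu[, t])
  wind <- array(rnorm(S * J * Tn), dim = c(S, J, Tn))
  p <- plogis(alpha[1] + alpha[2] * wind)
  y <- array(rbinom(S * J * Tn, size = rep(as.vector(N[, rep(1:Tn, each = J)]),
                                           1),
                    prob = as.vector(p)),
             dim = c(S, J, Tn))
  data <- nmix_data(y, site_covariates = cbind(forest = forest),
                    visit_covariates = list(wind = wind))
  structure(list(data = data,
                 truth = list(beta = beta, alpha = alpha, delta = delta,
                              N = N, mu = mu),
                 generating_model = spec, config = config, seed = seed),
            class = "nmix_sim")
}

#' Simulate a single-season repeated-count survey
#'
#' Draws forest cover, a per-dataset abundance slope, latent abundances
#' `N_i ~ Poisson(mu_i)`, visit-level wind, detection probabilities and
#' counts `y_ij ~ Binomial(N_i, p_ij)` under the scenario's generating
#' constants. Bit-reproducible given `(config, seed)`.
#'
#' @param config a [scenario_config()] with `n_seasons = 1`.
#' @param seed integer seed (defaults to the scenario's own).
#' @return a list of class `nmix_sim` with elements `data` ([nmix_data]),
#'   `truth` (generating coefficients and latent `N`), and
#'   `generating_model` (always the model-1 structure).
#' @export
simulate_single_season <- function(config, seed = config$seed) {
  if (config$n_seasons != 1)
    stop("use simulate_multi_season() for n_seasons > 1")
  simulate_scenario(config, seed)
}

#' Simulate a multi-season survey with temporally autocorrelated abundance
#'
#' Season one matches the single-season generator; later seasons evolve the
#' expected abundance by the site-specific growth rate
#' `log(psi[i, t]) = delta0 + delta1 * forest_i + delta2 * t` and draw fresh
#' `N[i, t] ~ Poisson(mu[i, t])`. The observation process is applied
#' independently each season. With one season and the same seed this reduces
#' exactly to the single-season generator.
#'
#' @param config a [scenario_config()] with `n_seasons >= 2` and a trend.
#' @param seed integer seed (defaults to the scenario's own).
#' @return a list of class `nmix_sim`; see [simulate_single_season()].
#' @export
simulate_multi_season <- function(config, seed = config$seed) {
  if (config$n_seasons < 2)
    stop("multi-season simulation requires n_seasons >= 2")
  simulate_scenario(config, seed)
}

#' The benchmark's scenario grid
#'
#' The six single-season site-count by detection combinations (4 visits), six
#' visit-count variants (8 and 16 visits by the three site counts, low
#' detection), and the twelve multi-season combinations (weak/strong trend by
#' detection by site count, 5 seasons), each tagged with the full-scale
#' replicate count of 100.
#'
#' @param seed base seed assigned to every preset.
#' @return named list of [scenario_config()] objects.
#' @export
scenario_presets <- function(seed = 1) {
  out <- list()
  for (det in c("low", "high"))
    for (S in c(15, 25, 50))
      out[[length(out) + 1]] <- scenario_config(S, 4, 1, det, "none", seed)
  for (J in c(8, 16))
    for (S in c(15, 25, 50))
      out[[length(out) + 1]] <- scenario_config(S, J, 1, "low", "none", seed)
  for (trend in c("weak", "strong"))
    for (det in c("low", "high"))
      for (S in c(15, 25, 50))
        out[[length(out) + 1]] <- scenario_config(S, 4, 5, det, trend, seed)
  names(out) <- vapply(out, scenario_label, "")
  out
}

#' Monte-Carlo calibration of a detection scenario
#'
#' Draws wind values from a standard normal and reports the mean and central
#' 95% range of the implied per-visit detection probabilities under the
#' scenario's generating coefficients. A self-test that the generating
#' constants reproduce the intended average detection levels (0.13 low,
#' 0.84 high).
#'
#' @param scenario `"low"` or `"high"`.
#' @param n_draws Monte-Carlo sample size.
#' @param seed optional integer seed.
#' @param alpha1 wind coefficient (default the study condition, 0.4).
#' @return list with `mean`, `lower`, `upper` (2.5/97.5 percentiles) and the
#'   coefficients used.
#' @examples
#' calibrate_detection_scenario("low", n_draws = 1e4, seed = 1)$mean
#' @export
calibrate_detection_scenario <- function(scenario, n_draws = 1e5,
                                         seed = NULL, alpha1 = 0.4) {
  a0 <- detection_intercept(scenario)
  if (!is.null(seed)) set.seed(seed)
  p <- plogis(a0 + alpha1 * rnorm(n_draws))
  list(mean = mean(p),
       lower = unname(quantile(p, 0.025)),
       upper = unname(quantile(p, 0.975)),
       alpha0 = a0, alpha1 = alpha1, n_draws = n_draws)
}

#' Write a simulated dataset as CSV counts plus a JSON truth sidecar
#'
#' @param sim an `nmix_sim` from the simulators.
#' @param path destination CSV path; the generating coefficients and latent
#'   abundances go to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "nmix_sim"))
  write_counts_csv(sim$data, path)
  jsonlite::write_json(
    list(beta = sim$truth$beta, alpha = sim$truth$alpha,
         delta = sim$truth$delta, N = sim$truth$N, seed = sim$seed,
         scenario = unclass(sim$config)[c("n_sites", "n_visits", "n_seasons",
                                          "detection", "trend")]),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
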