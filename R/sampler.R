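#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler: sitewise integer
#' random walks on the latent abundances and blockwise Gaussian random walks
#' on the coefficient vectors. Proposal scales may adapt during burn-in and
#' are frozen before any retained iteration, so retained chains come from a
#' fixed Metropolis kernel. All coefficients carry independent Normal(0, sd =
#' `prior_sd`) priors on their link scales.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iterations iterations per chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param burn_in_fraction fraction of each chain discarded, in `[0, 1)`.
#' @param base_seed integer seed; chain c uses `base_seed + c`.
#' @param proposal_scale_beta,proposal_scale_alpha,proposal_scale_delta
#'   initial random-walk standard deviations per coefficient block.
#' @param latent_proposal_halfwidth integer half-width d of the latent
#'   proposal `N' ~ Uniform({N-d, ..., N+d} \ {N})`.
#' @param latent_gibbs_interval every this many iterations each latent
#'   abundance is additionally refreshed by an exact draw from its truncated
#'   full conditional (0 disables). The local random walk alone mixes slowly
#'   across the joint abundance-detection ridge when detection probability is
#'   low; the periodic exact refresh removes that bottleneck while keeping
#'   the sampler a latent-state MCMC.
#' @param adapt adapt proposal scales during burn-in.
#' @param prior_sd prior standard deviation for all coefficients.
#' @return a list of class `nmix_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iterations = 10000, thin = 1,
                        burn_in_fraction = 0.5, base_seed = 1,
                        proposal_scale_beta = 0.1,
                        proposal_scale_alpha = 0.1,
                        proposal_scale_delta = 0.1,
                        latent_proposal_halfwidth = 3,
                        latent_gibbs_interval = 5,
                        adapt = TRUE, prior_sd = 2) {
  stopifnot(n_chains >= 1, n_iterations >= 2, thin >= 1,
            burn_in_fraction >= 0, burn_in_fraction < 1,
            latent_proposal_halfwidth >= 1, latent_gibbs_interval >= 0,
            prior_sd > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 thin = as.integer(thin),
                 burn_in_fraction = burn_in_fraction,
                 base_seed = as.integer(base_seed),
                 proposal_scale_beta = proposal_scale_beta,
                 proposal_scale_alpha = proposal_scale_alpha,
                 proposal_scale_delta = proposal_scale_delta,
                 latent_proposal_halfwidth = as.integer(latent_proposal_halfwidth),
                 latent_gibbs_interval = as.integer(latent_gibbs_interval),
                 adapt = isTRUE(adapt), prior_sd = prior_sd),
            class = "nmix_mcmc_config")
}

default_init <- function(data, spec) {
  nc <- n_coef(data, spec)
  list(beta = numeric(nc$beta), alpha = numeric(nc$alpha),
       delta = numeric(nc$delta),
       N = max_count_per_unit(data) + 1L)
}

#' Fit a binomial N-mixture model by MCMC
#'
#' Posterior sampling of the abundance coefficients (log link), detection
#' coefficients (logit link), growth coefficients (seasonal models) and the
#' latent per-site abundances. Latent abundances are initialized at one above
#' the site's maximum count and coefficients at zero, so the chain always
#' starts in the support. Runs are bit-reproducible given the configuration's
#' seed.
#'
#' @param data an [nmix_data] object.
#' @param spec a [model_spec()] object.
#' @param config an [mcmc_config()].
#' @param init optional list overriding the default initial state (elements
#'   `beta`, `alpha`, `delta`, `N`).
#' @param fix_coefficients if `TRUE`, only the latent abundances are updated
#'   and the coefficients stay at their initial values (used for validating
#'   the latent kernel against a brute-force posterior).
#' @return object of class `nmix_fit`: retained draws (`draws$beta`,
#'   `draws$alpha`, `draws$delta`, `draws$N`, rows = draws, chains stacked),
#'   `chain` and `iteration` indices, per-chain acceptance rates and adapted
#'   scales, plus the data, model and config.
#' @examples
#' sim <- simulate_single_season(scenario_config(n_sites = 10, seed = 1))
#' fit <- fit_nmixture(sim$data, candidate_models()$model1,
#'                     mcmc_config(n_iterations = 200, base_seed = 1))
#' fit
#' @export
fit_nmixture <- function(data, spec, config = mcmc_config(), init = NULL,
                         fix_coefficients = FALSE) {
  check_model_data(spec, data)
  stopifnot(inherits(config, "nmix_mcmc_config"))
  y <- unit_count_matrix(data)
  Xa <- abundance_design(data, spec)
  Xg <- growth_design(data, spec)
  Xd <- detection_design(data, spec)
  ini <- default_init(data, spec)
  if (!is.null(init))
    for (nm in intersect(names(init), names(ini)))
      if (!is.null(init[[nm]])) ini[[nm]] <- init[[nm]]
  ini$N <- as.integer(ini$N)

  chains <- vector("list", config$n_chains)
  for (c in seq_len(config$n_chains)) {
    set.seed(config$base_seed + c)
    chains[[c]] <- nmix_chain_cpp(
      y, Xa, Xg, Xd, data$n_sites, data$n_seasons,
      config$n_iterations, config$burn_in_fraction, config$thin,
      ini$beta, ini$alpha, ini$delta, ini$N, config$prior_sd,
      config$proposal_scale_beta, config$proposal_scale_alpha,
      config$proposal_scale_delta, config$latent_proposal_halfwidth,
      config$adapt, !fix_coefficients, config$latent_gibbs_interval)
  }

  nret <- nrow(chains[[1]]$N)
  nms <- coef_names(data, spec)
  draws <- list(
    beta = do.call(rbind, lapply(chains, `[[`, "beta")),
    alpha = do.call(rbind, lapply(chains, `[[`, "alpha")),
    delta = do.call(rbind, lapply(chains, `[[`, "delta")),
    N = do.call(rbind, lapply(chains, `[[`, "N")))
  colnames(draws$beta) <- nms$beta
  colnames(draws$alpha) <- nms$alpha
  if (length(nms$delta)) colnames(draws$delta) <- nms$delta

  maxy <- max_count_per_unit(data)
  if (any(sweep(draws$N, 2, maxy) < 0))
    stop("internal error: retained draw violates latent_N >= max count")

  structure(list(
    draws = draws,
    chain = rep(seq_len(config$n_chains), each = nret),
    iteration = rep(seq_len(nret), config$n_chains),
    acceptance = lapply(chains, `[[`, "acceptance"),
    scales = lapply(chains, `[[`, "scales"),
    data = data, model = spec, config = config),
    class = "nmix_fit")
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat(sprintf("N-mixture fit: %d retained draws (%d chain(s))\n",
              nrow(x$draws$beta), max(x$chain)))
  print(x$model)
  est <- colMeans(cbind(x$draws$beta, x$draws$alpha, x$draws$delta))
  cat("posterior means:\n")
  print(round(est, 3))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factors
#'
#' Classic between/within-chain variance form of the potential scale
#' reduction factor, computed per scalar coefficient. Values near 1 indicate
#' the chains are sampling the same distribution; values above about 1.1 are
#' conventionally flagged as non-converged.
#'
#' @param fit an [fit_nmixture()] result with at least two chains.
#' @return named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(fit) {
  stopifnot(inherits(fit, "nmix_fit"))
  m <- max(fit$chain)
  if (m < 2) stop("Gelman-Rubin diagnostic requires at least 2 chains")
  draws <- cbind(fit$draws$beta, fit$draws$alpha, fit$draws$delta)
  vapply(seq_len(ncol(draws)), function(k) {
    x <- split(draws[, k], fit$chain)
    n <- length(x[[1]])
    W <- mean(vapply(x, var, 0))
    B_over_n <- var(vapply(x, mean, 0))
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, 0, USE.NAMES = FALSE) -> r
  setNames(r, colnames(draws))
}

#' Posterior-predictive replicate counts
#'
#' For each retained draw s and observation (site, visit, season) simulates one
#' replicate count `y_rep ~ Binomial(N^{(s)}, p^{(s)})`. These replicates are
#' the input to [posterior_predictive_loss()].
#'
#' @param fit an [fit_nmixture()] result.
#' @param seed optional integer seed for the replicate draws.
#' @param max_draws optional cap on the number of posterior draws used; draws
#'   are taken at an even stride so both chains contribute.
#' @return integer matrix, draws x observations (observation columns in the
#'   same order as [conditional_pointwise_loglik()]).
#' @export
posterior_predictive_replicates <- function(fit, seed = NULL,
                                            max_draws = NULL) {
  stopifnot(inherits(fit, "nmix_fit"))
  idx <- seq_len(nrow(fit$draws$N))
  if (!is.null(max_draws) && max_draws < length(idx)) {
    stride <- ceiling(length(idx) / max_draws)
    idx <- seq(1L, length(idx), by = stride)
  }
  if (!is.null(seed)) set.seed(seed)
  pp_replicates_cpp(fit$draws$N[idx, , drop = FALSE],
                    fit$draws$alpha[idx, , drop = FALSE],
                    unit_count_matrix(fit$data),
                    detection_design(fit$data, fit$model))
}

# ---- plain-R single-sweep kernels -----------------------------------------
# Reference implementations of the two Metropolis updates the compiled
# sampler iterates; useful for stepwise inspection and as a second route in
# the kernel validation tests.

state_mu <- function(state, data, spec) {
  as.vector(multiseason_expected_abundance(state$beta, state$delta, data, spec))
}

state_p <- function(state, data, spec) {
  p <- detection_prob(state$alpha, data, spec)
  matrix(aperm(p, c(1, 3, 2)), nrow = data$n_sites * data$n_seasons)
}

#' One Metropolis sweep over the latent abundances
#'
#' Sitewise integer random-walk proposal `N' ~ Uniform({N-d,...,N+d} \ {N})`,
#' rejected outright below the site's maximum count, otherwise accepted with
#' the ratio of `Poisson(N'; mu) * prod_j Binomial(y_j; N', p_j)` to the
#' current value.
#'
#' @param state list with elements `beta`, `alpha`, `delta`, `N` (latent
#'   abundances as a sites x seasons matrix or unit vector).
#' @param data an [nmix_data] object.
#' @param spec a [model_spec()] object.
#' @param halfwidth proposal half-width d.
#' @return the state with an updated `N`.
#' @export
update_latent_abundance <- function(state, data, spec, halfwidth = 3) {
  check_model_data(spec, data)
  y <- unit_count_matrix(data)
  maxy <- max_count_per_unit(data)
  mu <- state_mu(state, data, spec)
  p <- state_p(state, data, spec)
  N <- as.integer(state$N)
  for (u in seq_along(N)) {
    d <- sample(c(-halfwidth:-1, 1:halfwidth), 1)
    Np <- N[u] + d
    if (Np < maxy[u]) next
    lr <- dpois(Np, mu[u], log = TRUE) - dpois(N[u], mu[u], log = TRUE) +
      sum(dbinom(y[u, ], Np, p[u, ], log = TRUE)) -
      sum(dbinom(y[u, ], N[u], p[u, ], log = TRUE))
    if (is.finite(lr) && (lr >= 0 || log(runif(1)) < lr)) N[u] <- Np
    else if (lr == Inf) N[u] <- Np
  }
  state$N <- array(N, dim = c(data$n_sites, data$n_seasons))
  state
}

#' One blockwise Metropolis sweep over the coefficients
#'
#' Gaussian random-walk proposals for the abundance block (Poisson likelihood
#' of the current latent abundances), the growth block (seasonal models) and
#' the detection block (binomial likelihood), each with an independent
#' Normal(0, `prior_sd`) prior.
#'
#' @inheritParams update_latent_abundance
#' @param scales named list of proposal standard deviations
#'   (`beta`, `alpha`, `delta`).
#' @param prior_sd prior standard deviation.
#' @return the state with updated coefficient blocks.
#' @export
update_coefficients <- function(state, data, spec,
                                scales = list(beta = 0.1, alpha = 0.1,
                                              delta = 0.1),
                                prior_sd = 2) {
  check_model_data(spec, data)
  y <- unit_count_matrix(data)
  N <- as.integer(state$N)
  lprior <- function(x) -0.5 * sum(x^2) / prior_sd^2

  pois_ll <- function(st) sum(dpois(N, state_mu(st, data, spec), log = TRUE))
  binom_ll <- function(st) {
    p <- state_p(st, data, spec)
    sum(dbinom(y, matrix(N, nrow(y), ncol(y)), p, log = TRUE))
  }

  # beta block
  cand <- state
  cand$beta <- state$beta + scales$beta * rnorm(length(state$beta))
  lr <- pois_ll(cand) - pois_ll(state) + lprior(cand$beta) - lprior(state$beta)
  if (lr >= 0 || log(runif(1)) < lr) state$beta <- cand$beta
  # delta block (seasonal)
  if (spec$seasonal && data$n_seasons > 1 && length(state$delta)) {
    cand <- state
    cand$delta <- state$delta + scales$delta * rnorm(length(state$delta))
    lr <- pois_ll(cand) - pois_ll(state) +
      lprior(cand$delta) - lprior(state$delta)
    if (lr >= 0 || log(runif(1)) < lr) state$delta <- cand$delta
  }
  # alpha block
  cand <- state
  cand$alpha <- state$alpha + scales$alpha * rnorm(length(state$alpha))
  lr <- binom_ll(cand) - binom_ll(state) +
    lprior(cand$alpha) - lprior(state$alpha)
  if (lr >= 0 || log(runif(1)) < lr) state$alpha <- cand$alpha
  state
}

# ---- draw persistence -----------------------------------------------------

#' Persist posterior draws to a columnar CSV plus a metadata sidecar
#'
#' One column per scalar parameter and latent unit, plus `chain` and
#' `iteration`; the sampler configuration and model specification are stored
#' in a JSON sidecar (`<path>.meta.json`) so the fit can be reloaded without
#' refitting.
#'
#' @param fit an [fit_nmixture()] result.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "nmix_fit"))
  Nn <- paste0("N_", seq_len(ncol(fit$draws$N)))
  df <- data.frame(chain = fit$chain, iteration = fit$iteration)
  for (m in c("beta", "alpha", "delta"))
    if (ncol(fit$draws[[m]]) > 0)
      df <- cbind(df, as.data.frame(fit$draws[[m]]))
  df <- cbind(df, setNames(as.data.frame(fit$draws$N), Nn))
  write.csv(df, path, row.names = FALSE)
  meta <- list(
    model = unclass(fit$model), config = unclass(fit$config),
    n_beta = ncol(fit$draws$beta), n_alpha = ncol(fit$draws$alpha),
    n_delta = ncol(fit$draws$delta),
    coef_names = list(beta = colnames(fit$draws$beta),
                      alpha = colnames(fit$draws$alpha),
                      delta = colnames(fit$draws$delta)),
    package_version = as.character(packageVersion("nmixwaic")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Reload posterior draws written by [write_draws()]
#'
#' @param path CSV path previously written by [write_draws()].
#' @param data the [nmix_data] the draws were fit to (required for computing
#'   criteria from the reloaded fit).
#' @return an object of class `nmix_fit`.
#' @export
read_draws <- function(path, data) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  df <- read.csv(path, check.names = FALSE)
  spec <- model_spec(meta$model$abundance, meta$model$detection,
                     meta$model$seasonal)
  cfg <- do.call(mcmc_config, meta$config[names(meta$config) != "class"])
  nb <- meta$n_beta; na <- meta$n_alpha; nd <- meta$n_delta
  off <- 2
  draws <- list(
    beta = as.matrix(df[, off + seq_len(nb), drop = FALSE]),
    alpha = as.matrix(df[, off + nb + seq_len(na), drop = FALSE]),
    delta = if (nd > 0) as.matrix(df[, off + nb + na + seq_len(nd), drop = FALSE])
            else matrix(numeric(0), nrow = nrow(df), ncol = 0),
    N = as.matrix(df[, grep("^N_", names(df)), drop = FALSE]))
  storage.mode(draws$N) <- "integer"
  dimnames(draws$N) <- NULL
  structure(list(draws = draws, chain = df$chain, iteration = df$iteration,
                 acceptance = NULL, scales = NULL, data = data,
                 model = spec, config = cfg),
            class = "nmix_fit")
}
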