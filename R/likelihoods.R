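#' Log probability mass of the binomial observation model
#'
#' Exact log pmf of `y` successes in `N` trials with success probability `p`.
#' The boundary cases are handled by exact case analysis through the
#' underlying pmf: at `p = 1` the result is 0 when `y = N` and `-Inf`
#' otherwise; at `p = 0` it is 0 when `y = 0` and `-Inf` otherwise.
#'
#' @param y,N non-negative integers with `y <= N` (vectorized).
#' @param p probability in `[0, 1]` (boundaries allowed).
#' @return log probability (vectorized).
#' @examples
#' log_binomial_pmf(2, 5, 0.5)  # log(10/32)
#' @export
log_binomial_pmf <- function(y, N, p) {
  if (any(y < 0 | N < 0 | y != round(y) | N != round(N)))
    stop("`y` and `N` must be non-negative integers")
  if (any(y > N)) stop("`y` must not exceed `N`")
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  dbinom(y, size = N, prob = p, log = TRUE)
}

#' Log probability mass of the Poisson abundance model
#'
#' @param N non-negative integer count (vectorized).
#' @param mu strictly positive rate (vectorized).
#' @return log probability (vectorized).
#' @examples
#' log_poisson_pmf(3, 2.5)
#' @export
log_poisson_pmf <- function(N, mu) {
  if (any(N < 0 | N != round(N)))
    stop("`N` must be a non-negative integer")
  if (any(mu <= 0)) stop("`mu` must be strictly positive")
  dpois(N, lambda = mu, log = TRUE)
}

#' Expected abundance per site under the log link
#'
#' `mu_i = exp(beta0 + sum_k beta_k x_ik)` over the abundance terms named in
#' the model specification.
#'
#' @param beta coefficient vector, length `1 + length(spec$abundance)`
#'   (intercept first).
#' @param data an [nmix_data] object.
#' @param spec an [model_spec()] object.
#' @return positive vector of length `n_sites`.
#' @export
abundance_mean <- function(beta, data, spec) {
  check_model_data(spec, data)
  X <- abundance_design(data, spec)
  if (length(beta) != ncol(X))
    stop("`beta` must have length ", ncol(X), " (intercept + abundance terms)")
  as.vector(exp(X %*% beta))
}

#' Per-visit detection probability under the logit link
#'
#' @param alpha coefficient vector, length `1 + length(spec$detection)`.
#' @param data an [nmix_data] object.
#' @param spec an [model_spec()] object.
#' @return array of probabilities in (0, 1) with `dim(data$counts)`.
#' @export
detection_prob <- function(alpha, data, spec) {
  check_model_data(spec, data)
  X <- detection_design(data, spec)
  if (length(alpha) != ncol(X))
    stop("`alpha` must have length ", ncol(X), " (intercept + detection terms)")
  p <- plogis(as.vector(X %*% alpha))
  # obs order is u + (j-1)*U with u season-major; undo to site x visit x season
  a <- array(p, dim = c(data$n_sites, data$n_seasons, data$n_visits))
  aperm(a, c(1, 3, 2))
}

#' Expected abundance trajectory for multi-season models
#'
#' Season-one means come from the abundance predictor; later seasons follow
#' the multiplicative growth recursion `mu[i, t] = psi[i, t] * mu[i, t-1]`
#' with `log(psi[i, t]) = delta0 + delta' x_i + delta_t * t`.
#'
#' @param beta abundance coefficients (season one).
#' @param delta growth coefficients: intercept, one per abundance term, then
#'   the season-index coefficient.
#' @param data an [nmix_data] object with `n_seasons >= 1`.
#' @param spec a seasonal [model_spec()] object.
#' @return positive matrix, sites x seasons.
#' @export
multiseason_expected_abundance <- function(beta, delta, data, spec) {
  stopifnot(inherits(data, "nmix_data"))
  mu1 <- abundance_mean(beta, data, spec)
  Tn <- data$n_seasons
  if (Tn == 1) return(matrix(mu1, ncol = 1))
  Xg <- growth_design(data, spec)
  if (length(delta) != ncol(Xg))
    stop("`delta` must have length ", ncol(Xg),
         " (intercept + abundance terms + season index)")
  psi <- matrix(exp(Xg %*% delta), nrow = data$n_sites)  # seasons 2..T
  mu <- matrix(NA_real_, nrow = data$n_sites, ncol = Tn)
  mu[, 1] <- mu1
  for (t in 2:Tn) mu[, t] <- psi[, t - 1] * mu[, t - 1]
  mu
}

#' Marginal log-likelihood of the counts by truncated summation
#'
#' Brute-force marginalization of the latent abundances: for each site (and
#' season) the Poisson-weighted binomial product is summed over
#' `N = max_j y_ij, ..., K`. Intended as an independent oracle for validating
#' the sampler on small problems; cost grows linearly in `K`.
#'
#' @param params list with elements `beta`, `alpha` and (seasonal) `delta`.
#' @param data an [nmix_data] object.
#' @param spec an [model_spec()] object.
#' @param K truncation bound; must be at least the maximum observed count.
#' @return scalar log-likelihood of all counts with `N` summed out.
#' @export
marginal_data_loglik <- function(params, data, spec, K) {
  check_model_data(spec, data)
  maxy <- max_count_per_unit(data)
  if (K < max(maxy)) stop("`K` must be at least the maximum observed count")
  mu <- as.vector(multiseason_expected_abundance(
    params$beta, params$delta, data, spec))
  p <- detection_prob(params$alpha, data, spec)
  y <- unit_count_matrix(data)
  pmat <- matrix(aperm(p, c(1, 3, 2)), nrow = nrow(y))
  total <- 0
  for (u in seq_len(nrow(y))) {
    Ns <- maxy[u]:K
    lp <- dpois(Ns, mu[u], log = TRUE)
    for (j in seq_len(ncol(y)))
      lp <- lp + dbinom(y[u, j], size = Ns, prob = pmat[u, j], log = TRUE)
    m <- max(lp)
    total <- total + (if (is.finite(m)) m + log(sum(exp(lp - m))) else -Inf)
  }
  total
}

new_pointwise_loglik <- function(values, unit_kind) {
  stopifnot(is.matrix(values),
            unit_kind %in% c("observation", "site", "site_season"))
  structure(list(values = values, unit_kind = unit_kind),
            class = "pointwise_loglik")
}

#' @export
print.pointwise_loglik <- function(x, ...) {
  cat(sprintf("pointwise log-likelihood: %d draws x %d %s units\n",
              nrow(x$values), ncol(x$values), x$unit_kind))
  invisible(x)
}

#' Conditional (observation-level) pointwise log-likelihood
#'
#' Entry (s, o) is the binomial log pmf of observation o under draw s's
#' latent abundance and detection probability, i.e. the likelihood
#' conditioned on the latent states. This is the matrix conditional WAIC is
#' computed from.
#'
#' @param fit an [fit_nmixture()] result.
#' @return a `pointwise_loglik` with `unit_kind = "observation"`; columns are
#'   ordered unit-major (site, then season), visits outermost.
#' @export
conditional_pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "nmix_fit"))
  y <- unit_count_matrix(fit$data)
  vals <- cond_loglik_cpp(fit$draws$N, fit$draws$alpha, y,
                          detection_design(fit$data, fit$model))
  if (anyNA(vals))
    stop("non-finite conditional log-likelihood entries")
  new_pointwise_loglik(vals, "observation")
}

#' Joint pointwise log-likelihood (observation and state process)
#'
#' Entry (s, u) sums the binomial log pmfs of unit u's visits and the Poisson
#' log pmf of its latent abundance given the abundance mean, so the
#' state-process fit enters the criterion. Unlike the conditional likelihood
#' it does not collapse to zero as detection probability approaches one: the
#' Poisson term survives.
#'
#' @param fit an [fit_nmixture()] result.
#' @return a `pointwise_loglik` with `unit_kind = "site"` (or
#'   `"site_season"` for multi-season fits).
#' @export
joint_pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "nmix_fit"))
  data <- fit$data; spec <- fit$model
  y <- unit_count_matrix(data)
  vals <- joint_loglik_cpp(fit$draws$N, fit$draws$beta, fit$draws$alpha,
                           fit$draws$delta, y,
                           abundance_design(data, spec),
                           growth_design(data, spec),
                           detection_design(data, spec),
                           data$n_sites, data$n_seasons)
  new_pointwise_loglik(vals,
                       if (data$n_seasons > 1) "site_season" else "site")
}
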