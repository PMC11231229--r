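# Small deterministic fixtures and memoised fits shared across test files.

tiny_counts <- function() {
  matrix(c(3L, 1L, 2L,
           0L, 2L, 1L,
           1L, 0L, 4L), nrow = 3, byrow = TRUE)
}

tiny_data <- function() {
  nmix_data(tiny_counts(),
            site_covariates = cbind(forest = c(-0.3, 0.1, 0.4)),
            visit_covariates = list(
              wind = matrix(c(0.5, -1, 0.2, 0, 1.2, -0.4, -0.1, 0.3, 0.8),
                            nrow = 3, byrow = TRUE)))
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small but real single-season fit reused by pointwise/criteria tests
small_fit <- function() {
  memo("small_fit", {
    sim <- simulate_single_season(scenario_config(n_sites = 8, seed = 42))
    fit_nmixture(sim$data, candidate_models()$model1,
                 mcmc_config(n_iterations = 400, base_seed = 5))
  })
}

# a fit whose detection probability is pushed against 1: strong simulated
# detection signal, intercept-only candidate
boundary_fit <- function() {
  memo("boundary_fit", {
    set.seed(9)
    S <- 6; J <- 4
    N <- rpois(S, 5) + 1L
    y <- matrix(rep(N, J), nrow = S)  # p = 1: every count equals N
    d <- nmix_data(y)
    fit_nmixture(d, model_spec(),
                 mcmc_config(n_iterations = 400, base_seed = 2),
                 init = list(alpha = 40, N = N),
                 fix_coefficients = TRUE)
  })
}

# scalar-loop reference for the conditional pointwise matrix
cond_loglik_oracle <- function(fit) {
  data <- fit$data
  y <- matrix(aperm(data$counts, c(1, 3, 2)),
              nrow = data$n_sites * data$n_seasons)
  ndr <- nrow(fit$draws$N)
  U <- nrow(y); J <- ncol(y)
  Xd <- nmixwaic:::detection_design(data, fit$model)
  out <- matrix(NA_real_, ndr, U * J)
  for (s in seq_len(ndr)) {
    p <- plogis(as.vector(Xd %*% fit$draws$alpha[s, ]))
    for (u in seq_len(U)) for (j in seq_len(J)) {
      o <- u + (j - 1) * U
      out[s, o] <- dbinom(y[u, j], fit$draws$N[s, u], p[o], log = TRUE)
    }
  }
  out
}
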