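test_that("identical configurations give bit-identical draws", {
  sim <- simulate_single_season(scenario_config(n_sites = 6, seed = 3))
  cfg <- mcmc_config(n_iterations = 300, base_seed = 11)
  f1 <- fit_nmixture(sim$data, candidate_models()$model1, cfg)
  f2 <- fit_nmixture(sim$data, candidate_models()$model1, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_nmixture(sim$data, candidate_models()$model1,
                     mcmc_config(n_iterations = 300, base_seed = 12))
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("retained draws never violate the latent support constraint", {
  sim <- simulate_single_season(scenario_config(n_sites = 10,
                                                detection = "low", seed = 8))
  fit <- fit_nmixture(sim$data, candidate_models()$model1,
                      mcmc_config(n_iterations = 600, base_seed = 4))
  maxy <- apply(sim$data$counts[, , 1], 1, max)
  expect_true(all(sweep(fit$draws$N, 2, maxy) >= 0))
  expect_equal(nrow(fit$draws$N), 600)  # 2 chains x 300 retained
})

test_that("with detection pinned near one the latent abundance equals the maximum count", {
  fit <- boundary_fit()
  # every count was generated as y = N with p ~ 1, so the posterior of N
  # must sit on max_j y_ij itself
  maxy <- apply(fit$data$counts[, , 1], 1, max)
  expect_true(all(abs(colMeans(fit$draws$N) - maxy) < 1))
  expect_true(all(fit$draws$N == matrix(maxy, nrow(fit$draws$N),
                                        length(maxy), byrow = TRUE)))
})

test_that("latent kernel matches the brute-force truncated posterior (TV < 0.02)", {
  y <- matrix(c(3L, 1L, 2L, 0L,
                1L, 0L, 2L, 1L), nrow = 2, byrow = TRUE)
  d <- nmix_data(y, site_covariates = cbind(forest = c(0.2, -0.3)),
                 visit_covariates = list(wind = matrix(0, 2, 4)))
  spec <- candidate_models()$model1
  pars <- list(beta = c(log(6), 0.5), alpha = c(qlogis(0.3), 0))
  K <- 120
  bf_pmf <- function(u) {
    mu <- abundance_mean(pars$beta, d, spec)[u]
    p <- detection_prob(pars$alpha, d, spec)[u, , 1]
    Ns <- max(y[u, ]):K
    lp <- dpois(Ns, mu, log = TRUE)
    for (j in 1:4) lp <- lp + dbinom(y[u, j], Ns, p[j], log = TRUE)
    full <- numeric(K + 1)
    full[Ns + 1] <- exp(lp - max(lp)) / sum(exp(lp - max(lp)))
    full
  }
  cfg <- mcmc_config(n_chains = 1, n_iterations = 1e5,
                     burn_in_fraction = 0.1, base_seed = 7)
  fit <- fit_nmixture(d, spec, cfg, init = pars, fix_coefficients = TRUE)
  for (u in 1:2) {
    emp <- tabulate(fit$draws$N[, u] + 1L, nbins = K + 1) /
      nrow(fit$draws$N)
    expect_lt(0.5 * sum(abs(emp - bf_pmf(u))), 0.02)
  }
})

test_that("plain-R latent sweep targets the same truncated posterior", {
  y <- matrix(c(2L, 0L, 1L, 1L), nrow = 1)
  d <- nmix_data(y)
  spec <- model_spec()
  pars <- list(beta = log(4), alpha = qlogis(0.4), delta = numeric(0))
  K <- 60
  mu <- 4; p <- 0.4
  Ns <- 2:K
  lp <- dpois(Ns, mu, log = TRUE)
  for (j in 1:4) lp <- lp + dbinom(y[1, j], Ns, p, log = TRUE)
  pmf <- numeric(K + 1)
  pmf[Ns + 1] <- exp(lp - max(lp)) / sum(exp(lp - max(lp)))

  set.seed(31)
  state <- list(beta = pars$beta, alpha = pars$alpha, delta = numeric(0),
                N = matrix(3L, 1, 1))
  draws <- integer(3e4)
  for (i in seq_along(draws)) {
    state <- update_latent_abundance(state, d, spec, halfwidth = 3)
    draws[i] <- state$N[1, 1]
  }
  emp <- tabulate(draws[-(1:2000)] + 1L, nbins = K + 1) / (length(draws) - 2000)
  expect_lt(0.5 * sum(abs(emp - pmf)), 0.02)
  # proposals below the maximum count are impossible
  expect_true(all(draws >= 2L))
})

test_that("plain-R coefficient sweep concentrates alpha near the moment estimate", {
  # flat data, intercept-only model, latent N held at truth: the detection
  # posterior should centre near logit(ybar / Nbar)
  set.seed(12)
  Ntrue <- rep(10L, 12)
  y <- matrix(rbinom(12 * 4, 10, 0.35), nrow = 12)
  d <- nmix_data(y)
  spec <- model_spec()
  state <- list(beta = 0, alpha = 0, delta = numeric(0),
                N = matrix(Ntrue, ncol = 1))
  keep <- numeric(3000)
  for (i in seq_along(keep)) {
    state <- update_coefficients(state, d, spec,
                                 scales = list(beta = 0.15, alpha = 0.15,
                                               delta = 0.1))
    keep[i] <- state$alpha
  }
  est <- mean(plogis(keep[-(1:500)]))
  expect_lt(abs(est - mean(y) / 10), 0.03)
})

test_that("Gelman-Rubin diagnostic has the classic limiting behaviour", {
  fit <- small_fit()
  # two identical chains: no between-chain variance, R-hat <= 1
  same <- fit
  n <- nrow(fit$draws$beta)
  half <- fit$draws$beta[seq_len(n / 2), , drop = FALSE]
  same$draws$beta <- rbind(half, half)
  same$draws$alpha <- rbind(fit$draws$alpha[seq_len(n / 2), , drop = FALSE],
                            fit$draws$alpha[seq_len(n / 2), , drop = FALSE])
  r <- gelman_rubin(same)
  expect_true(all(r <= 1))
  # chains stuck at distinct constants: R-hat explodes
  apart <- fit
  apart$draws$beta <- cbind(rep(c(0, 5), each = n / 2),
                            rep(c(1, -1), each = n / 2))
  expect_true(all(gelman_rubin(apart)[1:2] > 10))
  # well-mixed real fit agrees with the reference implementation
  cr <- coda::gelman.diag(coda::mcmc.list(
    coda::mcmc(fit$draws$beta[fit$chain == 1, ]),
    coda::mcmc(fit$draws$beta[fit$chain == 2, ])),
    autoburnin = FALSE, multivariate = FALSE)
  expect_equal(unname(gelman_rubin(fit)[1:2]), unname(cr$psrf[, 1]),
               tolerance = 0.05)
  one <- fit
  one$chain <- rep(1L, length(fit$chain))
  expect_error(gelman_rubin(one), "2 chains")
})

test_that("posterior-predictive replicates respect the degenerate detection limits", {
  fit <- small_fit()
  hi <- fit; hi$draws$alpha[] <- 0; hi$draws$alpha[, 1] <- 40  # p -> 1
  reps <- posterior_predictive_replicates(hi, seed = 1)
  U <- fit$data$n_sites
  for (j in 1:4)
    expect_identical(reps[, (j - 1) * U + seq_len(U)],
                     unname(hi$draws$N))
  lo <- fit; lo$draws$alpha[] <- 0; lo$draws$alpha[, 1] <- -40  # p -> 0
  expect_true(all(posterior_predictive_replicates(lo, seed = 1) == 0))
  # law of total expectation: mean replicate ~ mean of N * p
  reps2 <- posterior_predictive_replicates(fit, seed = 2)
  Xd <- nmixwaic:::detection_design(fit$data, fit$model)
  pmat <- plogis(fit$draws$alpha %*% t(Xd))
  expected <- colMeans(fit$draws$N[, rep(seq_len(U), 4)] * pmat)
  mc_sd <- sqrt(colMeans((fit$draws$N[, rep(seq_len(U), 4)] * pmat)^2)) /
    sqrt(nrow(reps2))
  expect_true(all(abs(colMeans(reps2) - expected) < 6 * mc_sd + 0.5))
})

test_that("streaming criterion summaries equal the matrix-path criteria", {
  fit <- small_fit()
  set.seed(77)
  fast <- nmixwaic:::score_candidate(fit, pp_seed = 77, pp_draws = NULL)
  slow_w <- waic_conditional(conditional_pointwise_loglik(fit))
  slow_j <- waic_joint(joint_pointwise_loglik(fit))
  slow_p <- posterior_predictive_loss(
    posterior_predictive_replicates(fit, seed = 77), fit$data)
  expect_equal(fast$WAIC$value, slow_w$value, tolerance = 1e-9)
  expect_equal(fast$WAIC$penalty_term, slow_w$penalty_term, tolerance = 1e-9)
  expect_equal(fast$WAICj$value, slow_j$value, tolerance = 1e-9)
  expect_equal(fast$PPLoss$value, slow_p$value, tolerance = 1e-9)
})

test_that("draws persist to CSV and reload without refitting", {
  fit <- small_fit()
  path <- file.path(tempdir(), "draws.csv")
  write_draws(fit, path)
  back <- read_draws(path, fit$data)
  expect_equal(back$draws$beta, fit$draws$beta, tolerance = 1e-12)
  expect_identical(back$draws$N, unname(fit$draws$N))
  expect_identical(back$model$abundance, fit$model$abundance)
  expect_equal(waic_joint(joint_pointwise_loglik(back))$value,
               waic_joint(joint_pointwise_loglik(fit))$value,
               tolerance = 1e-8)
  unlink(c(path, paste0(path, ".meta.json")))
})
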