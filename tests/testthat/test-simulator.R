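test_that("detection scenarios calibrate to the intended average probabilities", {
  low <- calibrate_detection_scenario("low", n_draws = 1e5, seed = 1)
  high <- calibrate_detection_scenario("high", n_draws = 1e5, seed = 2)
  expect_lt(abs(low$mean - 0.13), 0.01)
  expect_lt(abs(high$mean - 0.84), 0.01)
  # central 95% ranges near the intended (0.06-0.24) and (0.73-0.93)
  expect_lt(abs(low$lower - 0.06), 0.02)
  expect_lt(abs(low$upper - 0.24), 0.02)
  expect_lt(abs(high$upper - 0.93), 0.02)
  # without covariate spread the range collapses to the intercept point
  flat <- calibrate_detection_scenario("low", n_draws = 1e4, seed = 3,
                                       alpha1 = 0)
  expect_equal(flat$lower, flat$upper)
  expect_equal(flat$mean, 0.13, tolerance = 1e-9)
})

test_that("simulated counts are reproducible and respect y <= N", {
  cfg <- scenario_config(n_sites = 30, detection = "low", seed = 5)
  a <- simulate_single_season(cfg)
  b <- simulate_single_season(cfg)
  expect_identical(a$data$counts, b$data$counts)
  expect_identical(a$truth$N, b$truth$N)
  for (s in c(1, 9, 33)) {
    sim <- simulate_single_season(cfg, seed = s)
    expect_true(all(sim$data$counts[, , 1] <= sim$truth$N[, 1]))
    expect_true(all(sim$data$counts >= 0))
  }
  # the generating slope is drawn per dataset away from zero
  slopes <- sapply(1:20, function(s)
    simulate_single_season(cfg, seed = s)$truth$beta[2])
  expect_true(all(abs(slopes) >= 0.5 & abs(slopes) <= 1.5))
  expect_true(any(slopes > 0) && any(slopes < 0))
})

test_that("pooled simulated detection matches the printed scenario summaries", {
  pool <- function(det) {
    ps <- unlist(lapply(1:20, function(s) {
      sim <- simulate_single_season(
        scenario_config(n_sites = 200, detection = det, seed = 1000 + s))
      plogis(sim$truth$alpha[1] +
               sim$truth$alpha[2] * sim$data$visit_covariates$wind)
    }))
    c(mean(ps), quantile(ps, c(0.025, 0.975)))
  }
  lo <- pool("low"); hi <- pool("high")
  expect_lt(abs(lo[[1]] - 0.13), 0.01)
  expect_lt(abs(hi[[1]] - 0.84), 0.01)
  expect_true(lo[2] > 0.03 && lo[3] < 0.28)
  expect_true(hi[2] > 0.68 && hi[3] < 0.96)
})

test_that("empirical detection frequency converges to p over many visits", {
  sim <- simulate_single_season(
    scenario_config(n_sites = 5, n_visits = 1e4, detection = "high",
                    seed = 77))
  p <- plogis(sim$truth$alpha[1] +
                sim$truth$alpha[2] * sim$data$visit_covariates$wind[, , 1])
  N <- sim$truth$N[, 1]
  for (i in which(N > 0))
    expect_equal(mean(sim$data$counts[i, , 1] / N[i]), mean(p[i, ]),
                 tolerance = 0.01)
})

test_that("multi-season trajectories carry the trend and autocorrelation", {
  cfg <- scenario_config(n_sites = 100, n_seasons = 5, detection = "high",
                         trend = "strong", seed = 9)
  sim <- simulate_multi_season(cfg)
  # strong positive trend: expected abundance strictly increasing each season
  expect_true(all(diff(t(sim$truth$mu)) > 0))
  # neighbouring seasons share mu, so latent N are positively correlated
  N <- sim$truth$N
  expect_gt(cor(as.vector(N[, -5]), as.vector(N[, -1])), 0)
  expect_true(all(nmixwaic:::unit_count_matrix(sim$data) <=
                    rep(as.vector(N), 4)))
})

test_that("one-season multi-season generation reduces to the single-season path", {
  cfg1 <- scenario_config(n_sites = 12, detection = "low", seed = 13)
  a <- simulate_single_season(cfg1, seed = 99)
  b <- nmixwaic:::simulate_scenario(cfg1, seed = 99)
  expect_identical(a$data$counts, b$data$counts)
  expect_identical(a$truth, b$truth)
})

test_that("the preset grid matches the study design", {
  ps <- scenario_presets()
  single <- Filter(function(s) s$n_seasons == 1 && s$n_visits == 4, ps)
  visits <- Filter(function(s) s$n_visits > 4, ps)
  multi <- Filter(function(s) s$n_seasons > 1, ps)
  expect_length(single, 6)
  expect_length(visits, 6)
  expect_length(multi, 12)
  expect_true(all(vapply(multi, `[[`, 0L, "n_seasons") == 5))
  expect_setequal(unique(vapply(single, `[[`, 0L, "n_sites")), c(15, 25, 50))
  expect_setequal(unique(vapply(multi, `[[`, "", "trend")),
                  c("weak", "strong"))
  expect_true(all(vapply(ps, `[[`, 0L, "n_replicates") == 100))
})

test_that("simulated datasets round-trip through CSV with a truth sidecar", {
  sim <- simulate_single_season(scenario_config(n_sites = 7, seed = 21))
  path <- file.path(tempdir(), "sim.csv")
  write_simulation(sim, path)
  back <- read_counts_csv(path, site_covariates = "forest",
                          visit_covariates = "wind")
  expect_identical(back$counts, sim$data$counts)
  expect_equal(back$site_covariates[, "forest"],
               sim$data$site_covariates[, "forest"], tolerance = 1e-12)
  expect_equal(back$visit_covariates$wind, sim$data$visit_covariates$wind,
               tolerance = 1e-12)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$beta, sim$truth$beta, tolerance = 1e-9)
  unlink(c(path, paste0(path, ".truth.json")))
})
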