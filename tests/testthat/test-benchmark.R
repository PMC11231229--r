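small_mcmc <- function() mcmc_config(n_iterations = 300, base_seed = 1)

test_that("a replicate scores every candidate under every criterion", {
  sc <- scenario_config(n_sites = 8, seed = 50)
  r <- run_replicate(sc, 1, mcmc = small_mcmc(), pp_draws = 200)
  expect_equal(nrow(r), 4 * 3)  # 4 candidates x 3 criteria
  expect_setequal(unique(r$criterion), c("WAIC", "WAICj", "PPLoss"))
  expect_setequal(unique(r$candidate),
                  c("model1", "model2", "model3", "model4"))
  for (cr in unique(r$criterion)) {
    x <- r[r$criterion == cr, ]
    expect_setequal(x$rank, 1:4)
    expect_equal(sum(x$weight), 1, tolerance = 1e-9)
    expect_equal(x$value, x$fit_term + x$penalty_term, tolerance = 1e-8)
  }
  expect_true(all(is.finite(r$max_rhat)))
  # rerunning the same replicate reproduces every score exactly
  r2 <- run_replicate(sc, 1, mcmc = small_mcmc(), pp_draws = 200)
  expect_equal(r$value, r2$value, tolerance = 1e-12)
})

test_that("experiments tabulate accuracy per scenario and pool criteria", {
  scs <- list(scenario_config(n_sites = 6, seed = 60),
              scenario_config(n_sites = 9, seed = 70))
  ex <- run_experiment(scs, n_replicates = 3, mcmc = small_mcmc(),
                       pp_draws = 200, progress = FALSE)
  expect_s3_class(ex, "nmix_experiment")
  expect_equal(nrow(ex$results), 2 * 3 * 12)
  acc <- accuracy_summary(ex)
  expect_equal(nrow(acc$long), 2 * 3)
  expect_true(all(acc$long$accuracy >= 0 & acc$long$accuracy <= 1))
  expect_true(all(acc$long$n == 3))
  expect_equal(nrow(acc$pooled), 3)
  expect_equal(sort(unique(acc$pooled$criterion)),
               c("PPLoss", "WAIC", "WAICj"))
  # single replicate: accuracy is a Bernoulli outcome
  ex1 <- run_experiment(scs[1], n_replicates = 1, mcmc = small_mcmc(),
                        pp_draws = 200, progress = FALSE)
  expect_true(all(accuracy_summary(ex1)$long$accuracy %in% c(0, 1)))
  expect_error(accuracy_summary(
    structure(list(results = NULL), class = "nmix_experiment")), "no results")
})

test_that("reports round-trip to disk with a complete manifest", {
  sc <- scenario_config(n_sites = 6, seed = 80)
  ex <- run_experiment(sc, n_replicates = 2, mcmc = small_mcmc(),
                       pp_draws = 200, progress = FALSE)
  dir <- file.path(tempdir(), "nmix_report")
  files <- write_report(ex, dir)
  expect_true(all(file.exists(files)))
  res <- read.csv(files["results"])
  expect_equal(nrow(res), nrow(ex$results))
  man <- jsonlite::read_json(files["manifest"], simplifyVector = TRUE)
  expect_equal(man$n_replicates, 2)
  expect_equal(man$scenarios[[1]]$seed, 80)
  # replaying the manifest's scenario and seeds reproduces the table
  sc2 <- scenario_config(man$scenarios[[1]]$n_sites,
                         man$scenarios[[1]]$n_visits,
                         man$scenarios[[1]]$n_seasons,
                         man$scenarios[[1]]$detection,
                         man$scenarios[[1]]$trend,
                         seed = man$scenarios[[1]]$seed)
  ex2 <- run_experiment(sc2, n_replicates = man$n_replicates,
                        mcmc = do.call(mcmc_config, man$mcmc),
                        pp_draws = man$pp_draws, progress = FALSE)
  expect_equal(ex2$results$value, ex$results$value, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("checkpointed experiments resume without recomputation", {
  sc <- scenario_config(n_sites = 6, seed = 90)
  dir <- file.path(tempdir(), "nmix_ckpt")
  ex <- run_experiment(sc, n_replicates = 2, mcmc = small_mcmc(),
                       pp_draws = 200, checkpoint_dir = dir, progress = FALSE)
  expect_length(list.files(dir), 2)
  ex2 <- run_experiment(sc, n_replicates = 2, mcmc = small_mcmc(),
                        pp_draws = 200, checkpoint_dir = dir,
                        progress = FALSE)
  expect_identical(ex$results$value, ex2$results$value)
  unlink(dir, recursive = TRUE)
})

test_that("count CSV reader validates the schema with row numbers", {
  sim <- simulate_single_season(scenario_config(n_sites = 5, seed = 44))
  path <- file.path(tempdir(), "counts.csv")
  write_counts_csv(sim$data, path)
  back <- read_counts_csv(path, site_covariates = "forest",
                          visit_covariates = "wind")
  expect_identical(back$counts, sim$data$counts)

  df <- read.csv(path)
  df$count[3] <- -1
  write.csv(df, path, row.names = FALSE)
  expect_error(read_counts_csv(path, "forest", "wind"), "row.*3")

  df$count[3] <- 2
  df2 <- rbind(df, df[1, ])
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_counts_csv(path, "forest", "wind"), "duplicate")

  df3 <- df[-1, ]
  write.csv(df3, path, row.names = FALSE)
  expect_error(read_counts_csv(path, "forest", "wind"), "unbalanced")

  write.csv(df, path, row.names = FALSE)
  expect_error(read_counts_csv(path, "forest", character()), "unknown")
  expect_error(read_counts_csv(path, c("forest", "elev"), "wind"), "absent")

  # a covariate missing from the data but named by a candidate is a fit-time
  # error, not a read-time one
  write.csv(df[, setdiff(names(df), "forest")], path, row.names = FALSE)
  noforest <- read_counts_csv(path, character(), "wind")
  expect_error(fit_nmixture(noforest, candidate_models()$model1,
                            small_mcmc()),
               "not found")
  unlink(path)
})
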