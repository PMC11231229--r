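# The two benchmark grids used by the acceptance checks. They are computed
# once per test run (memoised) at the desk-scale protocol: 30 replicates per
# cell, 6,000 iterations per chain thinned by 2.

acceptance_single_grid <- function() {
  memo("acceptance_single_grid", {
    cells <- list()
    k <- 0
    for (det in c("low", "high"))
      for (S in c(15, 25, 50)) {
        k <- k + 1
        cells[[k]] <- scenario_config(S, 4, 1, det, "none", seed = 1000 * k)
      }
    ex <- run_experiment(cells, n_replicates = 30,
                         mcmc = mcmc_config(n_iterations = 6000, thin = 2),
                         pp_draws = 1000, progress = FALSE)
    accuracy_summary(ex)$long
  })
}

acceptance_multi_grid <- function() {
  memo("acceptance_multi_grid", {
    cells <- list()
    k <- 0
    for (trend in c("weak", "strong"))
      for (det in c("low", "high"))
        for (S in c(15, 25, 50)) {
          k <- k + 1
          cells[[k]] <- scenario_config(S, 4, 5, det, trend,
                                        seed = 50000 + 1000 * k)
        }
    ex <- run_experiment(cells, n_replicates = 30,
                         mcmc = mcmc_config(n_iterations = 6000, thin = 2),
                         pp_draws = 1000, progress = FALSE)
    accuracy_summary(ex)$long
  })
}
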