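#' Desk- and paper-scale benchmark profiles
#'
#' The desk profile (30 replicates per scenario cell, 6,000 iterations per
#' chain thinned by 2, predictive replicates capped at 1,000 draws) keeps the
#' full selection experiment within interactive runtimes while holding the
#' binomial Monte-Carlo standard error of each accuracy estimate near 0.09.
#' The paper-scale profile runs 100 replicates with 10,000 unthinned
#' iterations per chain, the full reference protocol.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param base_seed seed forwarded to [mcmc_config()].
#' @return list with `n_replicates`, `mcmc` ([mcmc_config()]) and
#'   `pp_draws`.
#' @export
benchmark_profile <- function(profile = c("desk", "paper"), base_seed = 1) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    list(n_replicates = 30,
         mcmc = mcmc_config(n_iterations = 6000, thin = 2,
                            base_seed = base_seed),
         pp_draws = 1000)
  } else {
    list(n_replicates = 100,
         mcmc = mcmc_config(n_iterations = 10000, base_seed = base_seed),
         pp_draws = NULL)
  }
}

# fast path: one streaming pass over the retained draws produces the
# summaries for all three criteria; identical estimator arithmetic to the
# matrix-path functions (asserted in the test suite).
score_candidate <- function(fit, pp_seed, pp_draws = NULL) {
  data <- fit$data; spec <- fit$model
  ndr <- nrow(fit$draws$N)
  stride <- if (is.null(pp_draws) || pp_draws >= ndr) 1L
            else ceiling(ndr / pp_draws)
  set.seed(pp_seed)
  s <- pointwise_streams_cpp(fit$draws$N, fit$draws$beta, fit$draws$alpha,
                             fit$draws$delta, unit_count_matrix(data),
                             abundance_design(data, spec),
                             growth_design(data, spec),
                             detection_design(data, spec),
                             data$n_sites, data$n_seasons, stride)
  unit_kind <- if (data$n_seasons > 1) "site_season" else "site"
  list(WAIC = waic_from_summaries("WAIC", s$cond_lpd, s$cond_var,
                                  "observation"),
       WAICj = waic_from_summaries("WAICj", s$joint_lpd, s$joint_var,
                                   unit_kind),
       PPLoss = pp_loss_from_summaries(s$pp_mean, s$pp_var,
                                       as.vector(unit_count_matrix(data))))
}

#' Simulate one dataset and score every candidate under every criterion
#'
#' Simulates replicate `replicate_index` of the scenario (seed =
#' `scenario$seed + replicate_index`), fits each candidate by MCMC (chain c
#' seeded `replicate seed + c`), and computes conditional WAIC, WAICj and
#' posterior-predictive loss for each fit. Convergence (max R-hat < 1.1) is
#' recorded per candidate; non-converged fits are flagged but still scored. A
#' candidate whose fit fails yields a failure record (NA scores) and the
#' remaining candidates proceed.
#'
#' @param scenario a [scenario_config()].
#' @param replicate_index positive integer.
#' @param candidates named list of [model_spec()] candidates; defaults to
#'   [candidate_models()] matched to the scenario's seasonality.
#' @param mcmc an [mcmc_config()]; its `base_seed` is replaced by the
#'   replicate seed.
#' @param pp_draws optional cap on posterior draws used for predictive
#'   replicates.
#' @return data frame with one row per candidate x criterion: `value`,
#'   `fit_term`, `penalty_term`, `weight`, `rank`, `converged`, `max_rhat`,
#'   `error`.
#' @export
run_replicate <- function(scenario, replicate_index, candidates = NULL,
                          mcmc = mcmc_config(), pp_draws = NULL) {
  stopifnot(inherits(scenario, "nmix_scenario"), replicate_index >= 1)
  if (is.null(candidates)) candidates <- candidate_models(scenario$n_seasons > 1)
  stopifnot(length(candidates) >= 1)
  rep_seed <- scenario$seed + as.integer(replicate_index)
  sim <- simulate_scenario(scenario, seed = rep_seed)
  cfg <- mcmc
  cfg$base_seed <- rep_seed

  per_cand <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    res <- tryCatch({
      fit <- fit_nmixture(sim$data, candidates[[k]], cfg)
      rhat <- gelman_rubin(fit)
      scores <- score_candidate(fit, pp_seed = rep_seed + 100L * k,
                                pp_draws = pp_draws)
      list(scores = scores, max_rhat = max(rhat), error = NA_character_)
    }, error = function(e) {
      list(scores = NULL, max_rhat = NA_real_, error = conditionMessage(e))
    })
    per_cand[[k]] <- res
  }

  rows <- list()
  for (crit in c("WAIC", "WAICj", "PPLoss")) {
    vals <- vapply(per_cand, function(r)
      if (is.null(r$scores)) NA_real_ else r$scores[[crit]]$value, 0)
    ok <- which(is.finite(vals))
    w <- rep(NA_real_, length(vals)); rk <- rep(NA_integer_, length(vals))
    if (length(ok)) {
      w[ok] <- akaike_weights(vals[ok])
      rk[ok] <- order(order(vals[ok]))
    }
    for (k in seq_along(candidates)) {
      r <- per_cand[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scenario_label(scenario),
        replicate = replicate_index,
        candidate = names(candidates)[k],
        criterion = crit,
        value = vals[k],
        fit_term = if (is.null(r$scores)) NA_real_ else r$scores[[crit]]$fit_term,
        penalty_term = if (is.null(r$scores)) NA_real_ else r$scores[[crit]]$penalty_term,
        weight = w[k], rank = rk[k],
        converged = if (is.na(r$max_rhat)) NA else r$max_rhat < 1.1,
        max_rhat = r$max_rhat,
        error = r$error)
    }
  }
  do.call(rbind, rows)
}

#' Run the full model-selection experiment over a scenario grid
#'
#' For every scenario and replicate, simulates a dataset, fits all
#' candidates, scores all criteria ([run_replicate()]) and collects the long
#' results table. Replicates are independent jobs keyed by their seed, so
#' results are identical regardless of execution order or parallelism; with a
#' checkpoint directory, completed replicates are reloaded instead of rerun.
#'
#' @param scenarios list of [scenario_config()] objects (or a single one).
#' @param n_replicates replicates per scenario.
#' @param candidates as in [run_replicate()].
#' @param mcmc an [mcmc_config()] template.
#' @param pp_draws cap on predictive-replicate draws (see
#'   [benchmark_profile()]).
#' @param n_cores parallel workers via `parallel::mclapply` (1 = serial).
#' @param checkpoint_dir optional directory for per-replicate result files.
#' @param progress print one line per scenario to stderr.
#' @return object of class `nmix_experiment`: `results` (long data frame),
#'   the scenario list, candidate names, and the configuration used.
#' @export
run_experiment <- function(scenarios, n_replicates = 30, candidates = NULL,
                           mcmc = mcmc_config(n_iterations = 4000),
                           pp_draws = 1000, n_cores = 1,
                           checkpoint_dir = NULL, progress = TRUE) {
  if (inherits(scenarios, "nmix_scenario")) scenarios <- list(scenarios)
  stopifnot(n_replicates >= 1)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, scenario_label, "")
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)

  one <- function(sc, r) {
    cand <- candidates
    if (is.null(cand)) cand <- candidate_models(sc$n_seasons > 1)
    if (!is.null(checkpoint_dir)) {
      f <- file.path(checkpoint_dir,
                     paste0(scenario_label(sc), "_rep", r, ".rds"))
      if (file.exists(f)) return(readRDS(f))
      out <- run_replicate(sc, r, cand, mcmc, pp_draws)
      saveRDS(out, f)
      return(out)
    }
    run_replicate(sc, r, cand, mcmc, pp_draws)
  }

  all_rows <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    t0 <- Sys.time()
    reps <- if (n_cores > 1) {
      parallel::mclapply(seq_len(n_replicates), function(r) one(sc, r),
                         mc.cores = n_cores)
    } else {
      lapply(seq_len(n_replicates), function(r) one(sc, r))
    }
    all_rows[[nm]] <- do.call(rbind, reps)
    if (progress)
      message(sprintf("[%s] %d replicates in %.1fs", nm, n_replicates,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  structure(list(results = do.call(rbind, all_rows),
                 scenarios = scenarios,
                 n_replicates = n_replicates,
                 generating_candidate = "model1",
                 mcmc = mcmc, pp_draws = pp_draws),
            class = "nmix_experiment")
}

#' Top-model accuracy tables from an experiment
#'
#' Accuracy is the proportion of replicates in which the generating candidate
#' ranks first under a criterion. Returns the long per-cell table (with
#' binomial standard errors, the mean weight given to the generating model,
#' and accuracy restricted to converged replicates), a wide site-count table
#' shaped like the benchmark's summary, and pooled per-criterion accuracies
#' over scenario groups.
#'
#' @param experiment an [run_experiment()] result.
#' @return list with elements `long`, `wide`, `pooled`.
#' @export
accuracy_summary <- function(experiment) {
  stopifnot(inherits(experiment, "nmix_experiment"))
  res <- experiment$results
  if (is.null(res) || nrow(res) == 0) stop("experiment holds no results")
  gen <- experiment$generating_candidate
  g <- res[res$candidate == gen, ]
  cells <- unique(res$scenario)

  long <- do.call(rbind, lapply(cells, function(sc) {
    do.call(rbind, lapply(unique(res$criterion), function(cr) {
      x <- g[g$scenario == sc & g$criterion == cr, ]
      top <- x$rank == 1
      n <- sum(!is.na(top))
      acc <- mean(top, na.rm = TRUE)
      conv <- x$converged %in% TRUE
      data.frame(scenario = sc, criterion = cr, n = n,
                 accuracy = acc,
                 se = sqrt(acc * (1 - acc) / max(n, 1)),
                 mean_weight = mean(x$weight, na.rm = TRUE),
                 accuracy_converged = if (any(conv))
                   mean(top[conv], na.rm = TRUE) else NA_real_,
                 n_converged = sum(conv))
    }))
  }))
  row.names(long) <- NULL

  scen_meta <- do.call(rbind, lapply(experiment$scenarios, function(s)
    data.frame(scenario = scenario_label(s), n_sites = s$n_sites,
               detection = s$detection, trend = s$trend,
               n_seasons = s$n_seasons)))
  long <- merge(long, scen_meta, by = "scenario", sort = FALSE)

  wide <- NULL
  if (length(unique(long$n_sites)) > 1) {
    wide <- stats::reshape(
      long[, c("trend", "detection", "criterion", "n_sites", "accuracy")],
      idvar = c("trend", "detection", "criterion"),
      timevar = "n_sites", direction = "wide")
    names(wide) <- sub("^accuracy\\.", "sites_", names(wide))
    wide <- wide[order(wide$trend, wide$detection, wide$criterion), ]
    row.names(wide) <- NULL
  }

  pooled <- do.call(rbind, lapply(split(long, long[, c("criterion", "trend")],
                                        drop = TRUE), function(x)
    data.frame(criterion = x$criterion[1], trend = x$trend[1],
               n_cells = nrow(x), accuracy = mean(x$accuracy),
               se = sqrt(sum(x$se^2)) / nrow(x))))
  row.names(pooled) <- NULL
  list(long = long, wide = wide, pooled = pooled)
}

#' Write an experiment's tables and a reproducibility manifest
#'
#' Emits `results.csv` (the long per-replicate table), `accuracy.csv`,
#' `pooled.csv` and `manifest.json` (scenario configurations, seeds, MCMC
#' settings and package version — enough to reproduce every number).
#'
#' @param experiment an [run_experiment()] result.
#' @param dir destination directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(experiment, dir) {
  stopifnot(inherits(experiment, "nmix_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  acc <- accuracy_summary(experiment)
  files <- c(results = file.path(dir, "results.csv"),
             accuracy = file.path(dir, "accuracy.csv"),
             pooled = file.path(dir, "pooled.csv"),
             manifest = file.path(dir, "manifest.json"))
  write.csv(experiment$results, files["results"], row.names = FALSE)
  write.csv(acc$long, files["accuracy"], row.names = FALSE)
  write.csv(acc$pooled, files["pooled"], row.names = FALSE)
  jsonlite::write_json(
    list(scenarios = lapply(experiment$scenarios, unclass),
         n_replicates = experiment$n_replicates,
         mcmc = unclass(experiment$mcmc),
         pp_draws = experiment$pp_draws,
         generating_candidate = experiment$generating_candidate,
         r_version = R.version.string,
         package_version = as.character(packageVersion("nmixwaic"))),
    files["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
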