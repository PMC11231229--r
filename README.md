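# nmixwaic

Bayesian model selection for binomial N-mixture models, built around a
joint-likelihood formulation of WAIC (WAICj) that keeps working where the
standard conditional WAIC goes blind.

## The problem

Ecologists estimate animal abundance from repeated unmarked counts: `S`
sites are each visited `J` times and the count `y[i, j]` is a binomial
thinning of a latent site abundance,

    log(mu_i)      = beta0 + beta1 * x_i + ...        (abundance, log link)
    N_i            ~ Poisson(mu_i)
    logit(p_ij)    = alpha0 + alpha1 * w_ij + ...     (detection, logit link)
    y_ij           ~ Binomial(N_i, p_ij)

Choosing among candidate models that put different covariates on abundance
versus detection is hard because the usual conditional WAIC only scores the
observation likelihood `P(y | N, p)`: as detection probability approaches 0
or 1 the binomial pmf approaches 1, the log predictive density approaches
0, and the abundance structure drops out of the criterion entirely. This
package implements three criteria side by side, from the same MCMC draws:

* **conditional WAIC** — `-2 lpd + 2 p_waic` over observation-level
  pointwise likelihoods;
* **WAICj** — the same estimator over the joint pointwise density
  `P(y_i | N_i) * P(N_i | mu_i)`, one unit per site (per site-season for
  multi-season models), so the Poisson state term survives at the
  detection boundaries;
* **posterior-predictive loss** — the squared-error Gelfand–Ghosh
  `D = G + P` from posterior-predictive replicate counts.

It also ships the full simulation benchmark: a generator for single-season
and temporally autocorrelated multi-season surveys under low (mean 0.13)
and high (mean 0.84) detection scenarios, a compiled
Metropolis-within-Gibbs sampler for the latent-state model, and an
experiment driver that measures how often each criterion ranks the
generating model first.

## Worked example

Simulate one high-detection survey (50 sites, 4 visits), fit the four
standard candidates, and compare them under WAICj:

```r
library(nmixwaic)
sim <- simulate_single_season(scenario_config(n_sites = 50,
                                              detection = "high", seed = 7))
cands <- candidate_models()
fits <- lapply(cands, function(m)
  fit_nmixture(sim$data, m,
               mcmc_config(n_iterations = 6000, thin = 2, base_seed = 7)))
rank_candidates(lapply(fits, function(f)
  waic_joint(joint_pointwise_loglik(f))))
```

```
  candidate criterion   value fit_term penalty_term   delta      weight rank
1    model1     WAICj 671.436  621.577      49.8593  0.0000 9.99983e-01    1
2    model2     WAICj 724.298  675.129      49.1693 52.8616 3.32081e-12    4
3    model3     WAICj 693.456  644.709      48.7467 22.0194 1.65400e-05    2
4    model4     WAICj 702.972  651.801      51.1707 31.5355 1.41953e-07    3
```

The generating structure (model 1: forest on abundance, wind on detection)
wins with essentially all the weight; its `value` is the criterion on the
deviance scale (`fit_term + penalty_term`, lower is better), `delta` the
gap to the best model, and `weight` the `exp(-delta/2)` Akaike-style
support. All four fits converged (every R-hat <= 1.006 by
`gelman_rubin()`). The detection calibration self-test reports what the
high scenario actually generates:

```r
calibrate_detection_scenario("high", n_draws = 1e5, seed = 1)
#> mean 0.8327, central 95% range (0.705, 0.920)
```

Data round-trip through a long-format CSV (`read_counts_csv()` /
`write_counts_csv()`), draws persist to a columnar CSV with a JSON metadata
sidecar (`write_draws()` / `read_draws()`), and `inst/scripts/nmix` exposes
`simulate`, `fit`, `select`, `benchmark` and `calibrate` subcommands for
shell use.

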