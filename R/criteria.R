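new_criterion_result <- function(criterion, fit_term, penalty_term,
                                 per_unit = NULL) {
  structure(list(criterion = criterion,
                 value = fit_term + penalty_term,
                 fit_term = fit_term, penalty_term = penalty_term,
                 per_unit = per_unit),
            class = "criterion_result")
}

#' @export
print.criterion_result <- function(x, ...) {
  cat(sprintf("%s = %.3f  (fit %.3f + penalty %.3f)\n", x$criterion,
              x$value, x$fit_term, x$penalty_term))
  invisible(x)
}

# shared WAIC estimator: lpd_u = log mean_s exp(ll[s,u]) (log-sum-exp),
# p_u = sample variance over draws (denominator n-1); deviance scale.
waic_from_summaries <- function(criterion, lpd, pvar, unit_kind) {
  res <- new_criterion_result(criterion,
                              fit_term = -2 * sum(lpd),
                              penalty_term = 2 * sum(pvar),
                              per_unit = -2 * lpd + 2 * pvar)
  res$lpd <- sum(lpd)
  res$p_waic <- sum(pvar)
  res$unit_kind <- unit_kind
  res
}

#' Conditional WAIC from an observation-level pointwise log-likelihood
#'
#' `WAIC = -2 * lpd + 2 * p_waic` where `lpd` sums, over observations, the
#' log of the across-draw mean predictive density (computed by log-sum-exp,
#' safe for entries as low as -700), and `p_waic` sums the across-draw sample
#' variances of the pointwise log-likelihood (denominator `draws - 1`).
#' Lower values indicate better expected predictive performance.
#'
#' @param loglik a `pointwise_loglik` with `unit_kind = "observation"` (from
#'   [conditional_pointwise_loglik()]) and at least two draws.
#' @return a `criterion_result` with elements `value`, `fit_term`
#'   (`-2 * lpd`), `penalty_term` (`2 * p_waic`) and `per_unit`.
#' @references Watanabe-Akaike information criterion for hierarchical models.
#' @export
waic_conditional <- function(loglik) {
  stopifnot(inherits(loglik, "pointwise_loglik"))
  if (loglik$unit_kind != "observation")
    stop("conditional WAIC expects observation-level pointwise units")
  if (nrow(loglik$values) < 2)
    stop("WAIC needs at least two posterior draws (variance undefined)")
  s <- col_lpd_var_cpp(loglik$values)
  waic_from_summaries("WAIC", s$lpd, s$var, loglik$unit_kind)
}

#' Joint-likelihood WAIC (WAICj) from a site-level pointwise log-likelihood
#'
#' The same estimator as [waic_conditional()] applied to the joint pointwise
#' matrix, whose unit is one site (one site-season for multi-season models):
#' each entry adds the Poisson log pmf of the latent abundance to the
#' binomial visit terms, so the state-process fit enters model selection and
#' the criterion keeps discriminating between abundance structures even when
#' detection probability approaches its boundaries.
#'
#' @param joint_loglik a `pointwise_loglik` with `unit_kind` `"site"` or
#'   `"site_season"` (from [joint_pointwise_loglik()]), >= 2 draws.
#' @return a `criterion_result` (criterion name `"WAICj"`).
#' @export
waic_joint <- function(joint_loglik) {
  stopifnot(inherits(joint_loglik, "pointwise_loglik"))
  if (!joint_loglik$unit_kind %in% c("site", "site_season"))
    stop("WAICj expects site or site-season pointwise units")
  if (nrow(joint_loglik$values) < 2)
    stop("WAIC needs at least two posterior draws (variance undefined)")
  s <- col_lpd_var_cpp(joint_loglik$values)
  waic_from_summaries("WAICj", s$lpd, s$var, joint_loglik$unit_kind)
}

pp_loss_from_summaries <- function(mu, sigma2, yvec) {
  new_criterion_result("PPLoss",
                       fit_term = sum((mu - yvec)^2),
                       penalty_term = sum(sigma2),
                       per_unit = (mu - yvec)^2 + sigma2)
}

#' Posterior-predictive loss (squared-error Gelfand-Ghosh form)
#'
#' `D_sel = G + P` with goodness-of-fit `G = sum_ij (mu_ij - y_ij)^2`, where
#' `mu_ij` is the across-draw mean of the posterior-predictive replicates,
#' and penalty `P = sum_ij sigma2_ij`, the across-draw sample variances of
#' the replicates. Lower is better; a model that reproduces the data exactly
#' with zero predictive variance scores 0.
#'
#' @param replicates integer matrix of replicate counts, draws x
#'   observations, from [posterior_predictive_replicates()].
#' @param data the [nmix_data] the replicates were generated for.
#' @return a `criterion_result` (criterion name `"PPLoss"`).
#' @export
posterior_predictive_loss <- function(replicates, data) {
  stopifnot(is.matrix(replicates), inherits(data, "nmix_data"))
  yvec <- as.vector(unit_count_matrix(data))
  if (ncol(replicates) != length(yvec))
    stop("replicate columns must match the number of observations")
  if (nrow(replicates) < 2)
    stop("posterior-predictive loss needs at least two replicate draws")
  mu <- colMeans(replicates)
  sigma2 <- colMeans(sweep(replicates, 2, mu)^2) *
    nrow(replicates) / (nrow(replicates) - 1)
  pp_loss_from_summaries(mu, sigma2, yvec)
}

#' Akaike-style model weights from criterion values
#'
#' `w_m = exp(-Delta_m / 2) / sum_k exp(-Delta_k / 2)` with
#' `Delta_m = value_m - min(value)`; the min-shift makes the computation
#' overflow-free and the weights invariant to adding a constant to every
#' value.
#'
#' @param values numeric vector of criterion values (deviance scale, lower
#'   is better); all must be finite.
#' @return weights summing to one.
#' @examples
#' akaike_weights(c(0, 2))
#' @export
akaike_weights <- function(values) {
  if (length(values) < 1 || any(!is.finite(values)))
    stop("`values` must be a non-empty vector of finite criterion values")
  w <- exp(-(values - min(values)) / 2)
  w / sum(w)
}

#' Rank candidate models under one criterion
#'
#' Ascending sort by criterion value (lower is better); exact ties keep the
#' candidates' listed order; Akaike-style weights are attached.
#'
#' @param results named list of `criterion_result` objects, one per
#'   candidate, all computed on the same data and criterion.
#' @return a `model_comparison` data frame with columns `candidate`,
#'   `criterion`, `value`, `fit_term`, `penalty_term`, `delta`, `weight`,
#'   `rank`.
#' @export
rank_candidates <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "criterion_result")))
  crit <- unique(vapply(results, `[[`, "", "criterion"))
  if (length(crit) != 1)
    stop("all candidates must be scored under the same criterion")
  nms <- names(results)
  if (is.null(nms)) nms <- paste0("candidate", seq_along(results))
  values <- vapply(results, `[[`, 0, "value")
  ord <- order(values)  # stable: ties keep list order
  out <- data.frame(
    candidate = nms,
    criterion = crit,
    value = values,
    fit_term = vapply(results, `[[`, 0, "fit_term"),
    penalty_term = vapply(results, `[[`, 0, "penalty_term"),
    delta = values - min(values),
    weight = akaike_weights(values),
    rank = order(ord),
    row.names = NULL)
  class(out) <- c("model_comparison", "data.frame")
  out
}
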