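#' Specify a candidate binomial N-mixture model
#'
#' A model specification names which covariates enter the abundance (log
#' link) and detection (logit link) linear predictors, and whether the model
#' carries the multi-season growth structure. Empty term vectors give
#' intercept-only predictors.
#'
#' For a seasonal model the growth rate psi for season t >= 2 is modelled as
#' `log(psi[i, t]) = delta0 + delta' x[i] + delta_t * t`, where the growth
#' covariates are the same site covariates named in `abundance`, so a
#' candidate without an abundance covariate also omits it from growth.
#'
#' @param abundance character vector of site-covariate names on abundance
#'   (may be empty).
#' @param detection character vector of covariate names on detection
#'   (site- or visit-level; may be empty).
#' @param seasonal logical; include the multiplicative growth structure for
#'   multi-season data.
#' @return an object of class `nmix_model`.
#' @examples
#' model_spec(abundance = "forest", detection = "wind")
#' @export
model_spec <- function(abundance = character(), detection = character(),
                       seasonal = FALSE) {
  structure(list(abundance = as.character(abundance),
                 detection = as.character(detection),
                 seasonal = isTRUE(seasonal)),
            class = "nmix_model")
}

#' @export
print.nmix_model <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = " + ") else "."
  cat(sprintf("N-mixture model: mu(%s) p(%s)%s\n", fmt(x$abundance),
              fmt(x$detection), if (x$seasonal) " [seasonal growth]" else ""))
  invisible(x)
}

#' The four standard single-covariate candidate models
#'
#' The candidate set used throughout the simulation benchmark: model 1 has
#' the site covariate on abundance and the visit covariate on detection (the
#' generating structure), model 2 is intercept-only everywhere, model 3 has
#' the site covariate on abundance only, model 4 the visit covariate on
#' detection only.
#'
#' @param seasonal logical; return the multi-season (growth-structured)
#'   versions of the same four candidates.
#' @param site_covariate,visit_covariate covariate names used by the
#'   candidates; defaults match the simulator's output.
#' @return named list of four [model_spec()] objects, the generating model
#'   first.
#' @export
candidate_models <- function(seasonal = FALSE, site_covariate = "forest",
                             visit_covariate = "wind") {
  list(
    model1 = model_spec(site_covariate, visit_covariate, seasonal),
    model2 = model_spec(character(), character(), seasonal),
    model3 = model_spec(site_covariate, character(), seasonal),
    model4 = model_spec(character(), visit_covariate, seasonal)
  )
}

check_model_data <- function(spec, data) {
  stopifnot(inherits(spec, "nmix_model"), inherits(data, "nmix_data"))
  bad_a <- setdiff(spec$abundance, colnames(data$site_covariates))
  if (length(bad_a))
    stop("abundance term(s) not found among site covariates: ",
         paste(bad_a, collapse = ", "))
  known <- c(colnames(data$site_covariates), names(data$visit_covariates))
  bad_d <- setdiff(spec$detection, known)
  if (length(bad_d))
    stop("detection term(s) not found among covariates: ",
         paste(bad_d, collapse = ", "))
  if (data$n_seasons > 1 && !spec$seasonal)
    stop("multi-season data require a seasonal model specification")
  invisible(TRUE)
}

# sites x (1 + n_abundance_terms) design for the first/only season
abundance_design <- function(data, spec) {
  X <- matrix(1, nrow = data$n_sites, ncol = 1 + length(spec$abundance))
  if (length(spec$abundance))
    X[, -1] <- data$site_covariates[, spec$abundance, drop = FALSE]
  X
}

# growth design for seasons t = 2..T, rows season-major (i + (t-2)*S):
# intercept, abundance site covariates, season index t
growth_design <- function(data, spec) {
  Tn <- data$n_seasons
  if (Tn < 2) return(matrix(numeric(0), nrow = 0, ncol = 0))
  S <- data$n_sites
  cols <- 2 + length(spec$abundance)
  X <- matrix(1, nrow = S * (Tn - 1), ncol = cols)
  for (t in 2:Tn) {
    rows <- (t - 2) * S + seq_len(S)
    if (length(spec$abundance))
      X[rows, 1 + seq_along(spec$abundance)] <-
        data$site_covariates[, spec$abundance, drop = FALSE]
    X[rows, cols] <- t
  }
  X
}

# (units * visits) x (1 + n_detection_terms) design, obs index o = u + (j-1)*U
detection_design <- function(data, spec) {
  U <- data$n_sites * data$n_seasons
  J <- data$n_visits
  X <- matrix(1, nrow = U * J, ncol = 1 + length(spec$detection))
  for (k in seq_along(spec$detection)) {
    nm <- spec$detection[k]
    if (nm %in% names(data$visit_covariates)) {
      v <- aperm(data$visit_covariates[[nm]], c(1, 3, 2))  # site, season, visit
      X[, 1 + k] <- as.vector(v)
    } else {
      X[, 1 + k] <- rep(rep(data$site_covariates[, nm], data$n_seasons), J)
    }
  }
  X
}

n_coef <- function(data, spec) {
  list(beta = 1L + length(spec$abundance),
       alpha = 1L + length(spec$detection),
       delta = if (spec$seasonal && data$n_seasons > 1)
         2L + length(spec$abundance) else 0L)
}

coef_names <- function(data, spec) {
  nb <- c("beta0", if (length(spec$abundance)) paste0("beta_", spec$abundance))
  na <- c("alpha0", if (length(spec$detection)) paste0("alpha_", spec$detection))
  nd <- if (spec$seasonal && data$n_seasons > 1)
    c("delta0", if (length(spec$abundance)) paste0("delta_", spec$abundance),
      "delta_t")
  else character()
  list(beta = nb, alpha = na, delta = nd)
}
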