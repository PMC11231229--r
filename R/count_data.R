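#' Repeated-count survey data for N-mixture modelling
#'
#' Bundles a site-by-visit (optionally by-season) matrix of non-negative
#' integer counts with site-level and visit-level covariates. This is the unit
#' of data every model-fitting and criterion function consumes.
#'
#' @param counts integer matrix (sites x visits) or 3-d array
#'   (sites x visits x seasons) of observed counts.
#' @param site_covariates optional numeric matrix or data frame with one row
#'   per site and named columns (e.g. `forest`).
#' @param visit_covariates optional named list of numeric arrays, each
#'   conforming to `dim(counts)` (e.g. `wind`), holding covariates that vary
#'   by visit.
#'
#' @return an object of class `nmix_data` with elements `counts` (always a
#'   3-d array), `site_covariates`, `visit_covariates`, `n_sites`,
#'   `n_visits`, `n_seasons`.
#' @examples
#' y <- matrix(c(1L, 0L, 2L, 1L, 0L, 1L), nrow = 3)
#' d <- nmix_data(y, site_covariates = cbind(forest = c(-0.2, 0.1, 0.4)))
#' d$n_sites
#' @export
nmix_data <- function(counts, site_covariates = NULL, visit_covariates = NULL) {
  if (is.matrix(counts)) counts <- array(counts, dim = c(dim(counts), 1L))
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("`counts` must be a sites x visits matrix or sites x visits x seasons array")
  if (anyNA(counts)) stop("`counts` must not contain missing values")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("all counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  ns <- dim(counts)[1]; nv <- dim(counts)[2]; nt <- dim(counts)[3]

  if (is.null(site_covariates)) {
    site_covariates <- matrix(numeric(0), nrow = ns, ncol = 0)
  } else {
    site_covariates <- as.matrix(site_covariates)
    if (nrow(site_covariates) != ns)
      stop("`site_covariates` must have one row per site")
    if (is.null(colnames(site_covariates)) && ncol(site_covariates) > 0)
      stop("`site_covariates` columns must be named")
  }
  if (is.null(visit_covariates)) visit_covariates <- list()
  if (length(visit_covariates) > 0 && is.null(names(visit_covariates)))
    stop("`visit_covariates` must be a named list")
  visit_covariates <- lapply(visit_covariates, function(v) {
    if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
    if (!identical(dim(v), dim(counts)))
      stop("each visit covariate must conform to dim(counts)")
    v
  })
  structure(
    list(counts = counts, site_covariates = site_covariates,
         visit_covariates = visit_covariates,
         n_sites = ns, n_visits = nv, n_seasons = nt),
    class = "nmix_data")
}

#' @export
print.nmix_data <- function(x, ...) {
  cat(sprintf("N-mixture count data: %d sites x %d visits x %d season(s)\n",
              x$n_sites, x$n_visits, x$n_seasons))
  cat(sprintf("  site covariates: %s\n",
              if (ncol(x$site_covariates)) paste(colnames(x$site_covariates), collapse = ", ") else "(none)"))
  cat(sprintf("  visit covariates: %s\n",
              if (length(x$visit_covariates)) paste(names(x$visit_covariates), collapse = ", ") else "(none)"))
  cat(sprintf("  total count: %d, max count: %d\n", sum(x$counts), max(x$counts)))
  invisible(x)
}

# units are stacked season-major: u = i + (t-1)*n_sites
unit_count_matrix <- function(data) {
  matrix(aperm(data$counts, c(1, 3, 2)),
         nrow = data$n_sites * data$n_seasons, ncol = data$n_visits)
}

max_count_per_unit <- function(data) {
  y <- unit_count_matrix(data)
  apply(y, 1, max)
}

#' Read repeated-count data from a long-format CSV
#'
#' The dialect has one row per (site, visit, season) with columns `site`,
#' `visit`, `season`, `count`, plus one column per covariate. Covariate roles
#' (site-level versus visit-level) are declared by the caller, never inferred.
#' The design must be balanced: every (site, visit, season) cell present
#' exactly once.
#'
#' @param path path to a CSV file.
#' @param site_covariates character vector of column names to treat as
#'   site-level covariates (must be constant within site).
#' @param visit_covariates character vector of column names to treat as
#'   visit-level covariates.
#' @return an [nmix_data] object.
#' @seealso [write_counts_csv()]
#' @export
read_counts_csv <- function(path, site_covariates = character(),
                            visit_covariates = character()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site", "visit", "season", "count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  declared <- c(site_covariates, visit_covariates)
  extra <- setdiff(names(df), c(needed, declared))
  if (length(extra))
    stop("unknown covariate columns (declare their role or drop them): ",
         paste(extra, collapse = ", "))
  absent <- setdiff(declared, names(df))
  if (length(absent))
    stop("declared covariate columns absent from file: ",
         paste(absent, collapse = ", "))

  bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop("non-integer or negative counts at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))

  sites <- sort(unique(df$site)); visits <- sort(unique(df$visit))
  seasons <- sort(unique(df$season))
  key <- paste(df$site, df$visit, df$season)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (site, visit, season) keys at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  if (nrow(df) != length(sites) * length(visits) * length(seasons))
    stop("unbalanced design: every (site, visit, season) cell must appear exactly once")

  i <- match(df$site, sites); j <- match(df$visit, visits)
  t <- match(df$season, seasons)
  dims <- c(length(sites), length(visits), length(seasons))
  idx <- cbind(i, j, t)
  counts <- array(0L, dim = dims)
  counts[idx] <- as.integer(df$count)

  sc <- NULL
  if (length(site_covariates)) {
    sc <- matrix(NA_real_, nrow = dims[1], ncol = length(site_covariates),
                 dimnames = list(NULL, site_covariates))
    for (nm in site_covariates) {
      agg <- tapply(df[[nm]], i, function(v) {
        if (length(unique(v)) > 1)
          stop("site covariate `", nm, "` varies within a site")
        v[1]
      })
      sc[, nm] <- as.numeric(agg)
    }
  }
  vc <- list()
  for (nm in visit_covariates) {
    a <- array(NA_real_, dim = dims)
    a[idx] <- df[[nm]]
    vc[[nm]] <- a
  }
  nmix_data(counts, site_covariates = sc, visit_covariates = vc)
}

#' Write repeated-count data to the long-format CSV dialect
#'
#' @param data an [nmix_data] object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @seealso [read_counts_csv()]
#' @export
write_counts_csv <- function(data, path) {
  stopifnot(inherits(data, "nmix_data"))
  grid <- expand.grid(site = seq_len(data$n_sites),
                      visit = seq_len(data$n_visits),
                      season = seq_len(data$n_seasons))
  idx <- as.matrix(grid)
  out <- data.frame(grid, count = data$counts[idx])
  for (nm in colnames(data$site_covariates))
    out[[nm]] <- data$site_covariates[grid$site, nm]
  for (nm in names(data$visit_covariates))
    out[[nm]] <- data$visit_covariates[[nm]][idx]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
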