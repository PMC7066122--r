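#' Container for one cohort's private data
#'
#' Bundles a site's feature matrix, binary endpoint and optional survival
#' follow-up. All downstream distributed computations consume this object
#' only inside site-local code; the coordinator sees aggregate messages.
#'
#' @param site_id character scalar identifying the cohort.
#' @param features numeric matrix, patients in rows, radiomic features in
#'   columns; column names are the feature identifiers. Entries may be `NA`.
#' @param outcome binary endpoint vector (0/1/`NA`), length `nrow(features)`.
#' @param time_years optional follow-up time in years (non-negative).
#' @param event optional event indicator (1 = death/event observed, 0 =
#'   censored), required when `time_years` is given.
#' @return An object of class `site_dataset` with elements `site_id`,
#'   `features`, `outcome`, `time_years`, `event` and `n` (number of rows).
#' @export
site_dataset <- function(site_id, features, outcome,
                         time_years = NULL, event = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features)) && ncol(features) > 0)
    stop("'features' must have column names (feature identifiers)")
  n <- nrow(features)
  if (length(outcome) != n)
    stop("'outcome' must have one entry per row of 'features'")
  if (!is.null(time_years)) {
    if (is.null(event))
      stop("'event' is required when 'time_years' is supplied")
    if (length(time_years) != n || length(event) != n)
      stop("survival vectors must have length nrow(features)")
    if (any(time_years < 0, na.rm = TRUE))
      stop("'time_years' must be non-negative")
  }
  structure(list(
    site_id = as.character(site_id),
    features = features,
    outcome = as.integer(outcome),
    time_years = time_years,
    event = if (!is.null(event)) as.integer(event) else NULL,
    n = n
  ), class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("<site_dataset '%s'> %d patients x %d features; outcome known for %d%s\n",
              x$site_id, x$n, ncol(x$features), sum(!is.na(x$outcome)),
              if (!is.null(x$time_years)) "; survival follow-up present" else ""))
  invisible(x)
}

feature_ids <- function(dataset) colnames(dataset$features)

#' Configuration for the multi-site synthetic cohort generator
#'
#' Describes a federation of cohorts whose features follow a block-correlated
#' factor model: feature j in cluster c is
#' `sqrt(rho_b) g + sqrt(rho_w - rho_b) u_c + sqrt(1 - rho_w) e_j`
#' with a shared global factor `g`, a cluster factor `u_c` and independent
#' noise, all standard normal per patient, so the expected within-cluster
#' correlation is `rho_w` (`within_cluster_corr`) and the between-cluster
#' correlation is `rho_b` (`between_cluster_corr`). A binary outcome is drawn
#' from a logistic model on designated features; survival times are
#' exponential with rate `baseline_event_rate * exp(linear predictor)`,
#' administratively censored at `censor_horizon_years`.
#'
#' @param num_sites number of cohorts (>= 1).
#' @param patients_per_site integer vector of cohort sizes (each >= 10),
#'   length `num_sites`.
#' @param num_clusters number of correlated feature blocks.
#' @param features_per_cluster features per block; total feature count is
#'   `num_clusters * features_per_cluster`.
#' @param within_cluster_corr expected correlation within a block, in [0, 1).
#' @param between_cluster_corr expected correlation across blocks, in
#'   [0, within_cluster_corr].
#' @param true_coefficients named numeric vector of logistic effect sizes;
#'   names are feature identifiers (at most one per cluster by convention,
#'   not enforced).
#' @param intercept intercept of the outcome model.
#' @param missing_fraction fraction of entries per feature column set missing
#'   completely at random, in [0, 0.5).
#' @param num_skewed_features number of (null) features replaced by a heavily
#'   right-skewed lognormal transform, to exercise the skewness QC rule.
#' @param site_mean_shift_sd standard deviation of additive per-site,
#'   per-feature mean shifts (scanner/protocol heterogeneity).
#' @param censor_horizon_years administrative censoring horizon (default 2).
#' @param baseline_event_rate exponential baseline hazard (events/year).
#' @param seed integer seed; the generator is reproducible given the seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(num_sites,
                             patients_per_site,
                             num_clusters = 5,
                             features_per_cluster = 4,
                             within_cluster_corr = 0.7,
                             between_cluster_corr = 0,
                             true_coefficients = c(f001 = 1),
                             intercept = 0,
                             missing_fraction = 0,
                             num_skewed_features = 0,
                             site_mean_shift_sd = 0,
                             censor_horizon_years = 2,
                             baseline_event_rate = 0.25,
                             seed = 1) {
  if (num_sites < 1) stop("'num_sites' must be >= 1")
  if (length(patients_per_site) != num_sites)
    stop("'patients_per_site' must have length 'num_sites'")
  if (any(patients_per_site < 10))
    stop("each cohort must have at least 10 patients")
  if (num_clusters < 1 || features_per_cluster < 1)
    stop("'num_clusters' and 'features_per_cluster' must be >= 1")
  if (within_cluster_corr < 0 || within_cluster_corr >= 1)
    stop("'within_cluster_corr' must be in [0, 1)")
  if (between_cluster_corr < 0 || between_cluster_corr > within_cluster_corr)
    stop("'between_cluster_corr' must be in [0, within_cluster_corr]")
  if (missing_fraction < 0 || missing_fraction >= 0.5)
    stop("'missing_fraction' must be in [0, 0.5)")
  if (censor_horizon_years <= 0) stop("'censor_horizon_years' must be > 0")
  if (baseline_event_rate <= 0) stop("'baseline_event_rate' must be > 0")
  p <- num_clusters * features_per_cluster
  ids <- sprintf("f%03d", seq_len(p))
  if (length(true_coefficients) > 0) {
    if (is.null(names(true_coefficients)) || any(names(true_coefficients) == ""))
      stop("'true_coefficients' must be a named vector of feature effects")
    bad <- setdiff(names(true_coefficients), ids)
    if (length(bad) > 0)
      stop("unknown feature id(s) in 'true_coefficients': ",
           paste(bad, collapse = ", "))
  }
  if (num_skewed_features > p - length(true_coefficients))
    stop("'num_skewed_features' exceeds the number of null features")
  structure(list(
    num_sites = as.integer(num_sites),
    patients_per_site = as.integer(patients_per_site),
    num_clusters = as.integer(num_clusters),
    features_per_cluster = as.integer(features_per_cluster),
    within_cluster_corr = within_cluster_corr,
    between_cluster_corr = between_cluster_corr,
    true_coefficients = true_coefficients,
    intercept = intercept,
    missing_fraction = missing_fraction,
    num_skewed_features = as.integer(num_skewed_features),
    site_mean_shift_sd = site_mean_shift_sd,
    censor_horizon_years = censor_horizon_years,
    baseline_event_rate = baseline_event_rate,
    seed = as.integer(seed),
    feature_ids = ids
  ), class = "generator_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-site federation
#'
#' Draws one `site_dataset` per cohort under the factor model described in
#' [generator_config()]. The outcome linear predictor uses the standard-scale
#' feature values before site mean shifts are added, so site heterogeneity
#' perturbs the observed features without changing the outcome model.
#'
#' @param config a `generator_config`.
#' @return A list of `site_dataset` objects, one per site, named by site id.
#' @export
generate_federation <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ids <- config$feature_ids
  p <- length(ids)
  cluster_of <- rep(seq_len(config$num_clusters),
                    each = config$features_per_cluster)
  rho_w <- config$within_cluster_corr
  rho_b <- config$between_cluster_corr
  beta <- config$true_coefficients
  skew_ids <- setdiff(ids, names(beta))
  skew_ids <- utils::tail(skew_ids, config$num_skewed_features)

  with_seed(config$seed, {
    sites <- vector("list", config$num_sites)
    for (k in seq_len(config$num_sites)) {
      n <- config$patients_per_site[k]
      g <- stats::rnorm(n)
      u <- matrix(stats::rnorm(n * config$num_clusters), n)
      eps <- matrix(stats::rnorm(n * p), n)
      x0 <- sqrt(rho_b) * g +
        sqrt(rho_w - rho_b) * u[, cluster_of, drop = FALSE] +
        sqrt(1 - rho_w) * eps
      colnames(x0) <- ids

      lp <- rep(config$intercept, n)
      if (length(beta) > 0)
        lp <- lp + drop(x0[, names(beta), drop = FALSE] %*% beta)
      outcome <- stats::rbinom(n, 1, stats::plogis(lp))
      raw_t <- stats::rexp(n, rate = config$baseline_event_rate * exp(lp))
      event <- as.integer(raw_t <= config$censor_horizon_years)
      time_years <- pmin(raw_t, config$censor_horizon_years)

      x <- x0
      if (config$site_mean_shift_sd > 0) {
        shift <- stats::rnorm(p, 0, config$site_mean_shift_sd)
        x <- sweep(x, 2, shift, `+`)
      }
      ds <- site_dataset(sprintf("site%02d", k), x, outcome,
                         time_years = time_years, event = event)
      if (length(skew_ids) > 0)
        ds <- inject_skew(ds, skew_ids, severity = 2.5)
      if (config$missing_fraction > 0)
        ds <- inject_missingness(ds, ids, config$missing_fraction,
                                 seed = stats::runif(1, 1, 2^30))
      sites[[k]] <- ds
    }
    names(sites) <- vapply(sites, function(s) s$site_id, character(1))
    sites
  })
}

#' Set feature entries missing completely at random
#'
#' For each named feature column, exactly `round(fraction * n)` entries are
#' set to `NA`, chosen uniformly at random; other columns are untouched.
#'
#' @param dataset a `site_dataset`.
#' @param ids feature identifiers to degrade.
#' @param fraction fraction of entries per column to remove, in [0, 1).
#' @param seed integer seed for the missingness mask (the caller's RNG state
#'   is restored afterwards).
#' @return The modified `site_dataset`.
#' @export
inject_missingness <- function(dataset, ids, fraction, seed = 1) {
  stopifnot(inherits(dataset, "site_dataset"))
  if (fraction < 0 || fraction >= 1) stop("'fraction' must be in [0, 1)")
  bad <- setdiff(ids, feature_ids(dataset))
  if (length(bad) > 0)
    stop("unknown feature id(s): ", paste(bad, collapse = ", "))
  m <- round(fraction * dataset$n)
  if (m == 0 || length(ids) == 0) return(dataset)
  with_seed(seed, {
    for (id in ids) {
      rows <- sample.int(dataset$n, m)
      dataset$features[rows, id] <- NA_real_
    }
  })
  dataset
}

#' Give features a heavily right-skewed distribution
#'
#' Replaces each named feature by `exp(severity * z)` where `z` is the
#' standardized original; for `severity >= 2` the sample skewness of the
#' transformed feature exceeds 5 with high probability at n >= 100
#' (lognormal skewness grows rapidly with the log-scale sd). Missing entries
#' stay missing.
#'
#' @param dataset a `site_dataset`.
#' @param ids feature identifiers to transform.
#' @param severity log-scale standard deviation of the transform (> 0).
#' @return The modified `site_dataset`.
#' @export
inject_skew <- function(dataset, ids, severity = 2.5) {
  stopifnot(inherits(dataset, "site_dataset"))
  if (severity <= 0) stop("'severity' must be > 0")
  bad <- setdiff(ids, feature_ids(dataset))
  if (length(bad) > 0)
    stop("unknown feature id(s): ", paste(bad, collapse = ", "))
  for (id in ids) {
    x <- dataset$features[, id]
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    dataset$features[, id] <- exp(severity * (x - mu) / s)
  }
  dataset
}
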