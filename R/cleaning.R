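#' Quality-control exclusion thresholds
#'
#' Features with more than `missing_max` missing values or with absolute
#' sample skewness above `skew_max` are excluded from modelling. Both
#' comparisons are strict, so boundary values are retained.
#'
#' @param missing_max maximum tolerated missing fraction (default 0.20).
#' @param skew_max maximum tolerated |skewness| (default 5).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(missing_max = 0.20, skew_max = 5.0) {
  if (missing_max <= 0 || skew_max <= 0)
    stop("thresholds must be positive")
  structure(list(missing_max = missing_max, skew_max = skew_max),
            class = "qc_thresholds")
}

qc_flags <- function(missing_fraction, skewness, thresholds, signed_skew) {
  skew_stat <- if (signed_skew) skewness else abs(skewness)
  list(missing = missing_fraction > thresholds$missing_max,
       skew = !is.na(skew_stat) & skew_stat > thresholds$skew_max)
}

qc_report <- function(excl_missing, excl_skew, site = "all") {
  out <- rbind(
    if (any(excl_missing))
      data.frame(feature = names(which(excl_missing)), rule = "missing",
                 site = site),
    if (any(excl_skew))
      data.frame(feature = names(which(excl_skew)), rule = "skewness",
                 site = site)
  )
  if (is.null(out))
    out <- data.frame(feature = character(0), rule = character(0),
                      site = character(0))
  out
}

#' Centralized quality-control feature exclusion
#'
#' Missing fraction and skewness are evaluated on the rows of all sites
#' concatenated; a feature is excluded iff its missing fraction strictly
#' exceeds `missing_max` or its |skewness| strictly exceeds `skew_max`.
#'
#' @param sites list of `site_dataset` objects with identical feature lists.
#' @param thresholds a `qc_thresholds`.
#' @param signed_skew if `TRUE`, compare the signed skewness instead of its
#'   absolute value (only right-skewed features are then excluded).
#' @return An object of class `qc_exclusion`: `excluded` (character vector)
#'   and a `report` data frame (`feature`, `rule`, `site`).
#' @export
qc_exclude_centralized <- function(sites, thresholds = qc_thresholds(),
                                   signed_skew = FALSE) {
  ids <- feature_ids(sites[[1]])
  for (s in sites)
    if (!identical(feature_ids(s), ids))
      stop("sites have inconsistent feature lists")
  x <- do.call(rbind, lapply(sites, `[[`, "features"))
  miss <- colMeans(is.na(x))
  skew <- apply(x, 2, g1_skewness)
  fl <- qc_flags(miss, skew, thresholds, signed_skew)
  structure(list(
    excluded = sort(names(which(fl$missing | fl$skew))),
    report = qc_report(fl$missing, fl$skew),
    mode = "centralized"
  ), class = "qc_exclusion")
}

#' Distributed quality-control feature exclusion
#'
#' Each site applies both QC rules to its own missing fractions and
#' skewness (as carried by its `moment_summary`); the excluded set is the
#' union over sites. The union rule is conservative: a feature failing QC in
#' any single cohort is dropped everywhere, so adding a site can only grow
#' the excluded set.
#'
#' @param summaries list of `moment_summary` objects.
#' @inheritParams qc_exclude_centralized
#' @return An object of class `qc_exclusion` whose `report` lists, per
#'   excluded feature, every site/rule pair that triggered it.
#' @export
qc_exclude_distributed <- function(summaries, thresholds = qc_thresholds(),
                                   signed_skew = FALSE) {
  stopifnot(length(summaries) >= 1)
  reports <- lapply(summaries, function(s) {
    miss <- s$missing_count / (s$n_per_feature + s$missing_count)
    fl <- qc_flags(miss, s$skewness, thresholds, signed_skew)
    qc_report(fl$missing, fl$skew, site = s$site_id)
  })
  report <- do.call(rbind, reports)
  structure(list(
    excluded = sort(unique(report$feature)),
    report = report,
    mode = "distributed"
  ), class = "qc_exclusion")
}

#' Write a QC exclusion report to JSON
#'
#' @param exclusion a `qc_exclusion`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(exclusion, path) {
  jsonlite::write_json(list(mode = exclusion$mode,
                            excluded = exclusion$excluded,
                            triggers = exclusion$report),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
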