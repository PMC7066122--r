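#' Write a federation to per-site CSV files
#'
#' One CSV per site: first column `patient_id`, then the feature columns,
#' then `outcome`, `time_years`, `event`. Missing entries are written as
#' empty fields. A JSON sidecar (`federation.json`) records the generating
#' configuration, including the true coefficients, when one is supplied.
#'
#' @param sites list of `site_dataset` objects.
#' @param dir output directory (created if needed).
#' @param config optional `generator_config` to record in the sidecar.
#' @return Invisibly, the paths of the written CSV files.
#' @export
write_federation <- function(sites, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(sites, function(s) {
    df <- data.frame(patient_id = sprintf("%s_p%04d", s$site_id, seq_len(s$n)),
                     s$features, check.names = FALSE)
    df$outcome <- s$outcome
    if (!is.null(s$time_years)) {
      df$time_years <- s$time_years
      df$event <- s$event
    }
    path <- file.path(dir, paste0(s$site_id, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, na = "")
    path
  }, character(1))
  if (!is.null(config)) {
    side <- unclass(config)
    side$true_coefficients <- as.list(side$true_coefficients)
    jsonlite::write_json(side, file.path(dir, "federation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read one cohort from CSV
#'
#' Inverse of [write_federation()] for a single site file.
#'
#' @param path CSV file with a `patient_id` column, feature columns and an
#'   `outcome` column; optional `time_years` and `event` columns.
#' @param site_id cohort identifier; defaults to the file name.
#' @return A `site_dataset`.
#' @export
read_site_csv <- function(path, site_id = NULL) {
  if (is.null(site_id))
    site_id <- sub("\\.csv$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- intersect(c("patient_id", "outcome", "time_years", "event"),
                    names(df))
  if (!all(c("patient_id", "outcome") %in% meta))
    stop("site CSV must contain 'patient_id' and 'outcome' columns: ", path)
  feats <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(feats) <- df$patient_id
  site_dataset(site_id, feats, df$outcome,
               time_years = if ("time_years" %in% meta) df$time_years,
               event = if ("event" %in% meta) df$event)
}
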