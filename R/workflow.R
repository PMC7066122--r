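#' Workflow configuration for the leave-one-cohort-out comparison
#'
#' Houses every workflow constant: QC thresholds (20% missing, skewness 5),
#' the 0.6 correlation cutoff for clustering, the 0.05 FDR gate of the
#' centralized selection, the 80% weighted vote threshold of the distributed
#' selection, and the Newton tolerance of the fitters.
#'
#' @param endpoint `"binary_outcome"` (use the outcome column as-is) or
#'   `"survival_2y"` (label = event before `horizon`; subjects censored
#'   before the horizon without an event have unknown status and are
#'   excluded from modelling).
#' @param mode `"both"` (default), `"centralized"` or `"distributed"`.
#' @param qc a `qc_thresholds`.
#' @param corr_cutoff clustering correlation cutoff (default 0.6).
#' @param fdr centralized selection FDR gate (default 0.05).
#' @param vote_threshold distributed selection rate (default 0.8).
#' @param glore_tol Newton convergence tolerance (default 1e-8).
#' @param max_iter maximum Newton iterations (default 25).
#' @param rho G-rho weight exponent for the survival comparison (default 0).
#' @param horizon survival horizon in years (default 2).
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic given the data).
#' @return An object of class `workflow_config`.
#' @export
workflow_config <- function(endpoint = c("binary_outcome", "survival_2y"),
                            mode = c("both", "centralized", "distributed"),
                            qc = qc_thresholds(),
                            corr_cutoff = 0.6,
                            fdr = 0.05,
                            vote_threshold = 0.8,
                            glore_tol = 1e-8,
                            max_iter = 25,
                            rho = 0,
                            horizon = 2,
                            seed = 1) {
  endpoint <- match.arg(endpoint)
  mode <- match.arg(mode)
  stopifnot(corr_cutoff > 0, corr_cutoff < 1, fdr > 0, fdr < 1,
            vote_threshold > 0, vote_threshold <= 1, glore_tol > 0,
            max_iter >= 1, horizon > 0)
  structure(list(endpoint = endpoint, mode = mode, qc = qc,
                 corr_cutoff = corr_cutoff, fdr = fdr,
                 vote_threshold = vote_threshold, glore_tol = glore_tol,
                 max_iter = max_iter, rho = rho, horizon = horizon,
                 seed = as.integer(seed)),
            class = "workflow_config")
}

# Resolve the modelling label for the configured endpoint and drop subjects
# with unknown status.
prepare_endpoint <- function(dataset, config) {
  if (config$endpoint == "survival_2y") {
    if (is.null(dataset$time_years))
      stop("site '", dataset$site_id, "' has no survival data")
    y <- ifelse(dataset$event == 1 & dataset$time_years <= config$horizon, 1L,
                ifelse(dataset$time_years >= config$horizon, 0L, NA_integer_))
  } else {
    y <- dataset$outcome
  }
  keep <- !is.na(y)
  site_dataset(dataset$site_id,
               dataset$features[keep, , drop = FALSE],
               y[keep],
               time_years = dataset$time_years[keep],
               event = if (!is.null(dataset$event)) dataset$event[keep])
}

# One arm (centralized or distributed) of the training pipeline:
# QC -> z-score -> correlation -> clustering -> representative selection
# -> multivariate logistic fit.
train_centralized <- function(train, config) {
  ids <- feature_ids(train[[1]])
  qc <- qc_exclude_centralized(train, config$qc)
  retained <- setdiff(ids, qc$excluded)
  x <- do.call(rbind, lapply(train, function(s)
    s$features[, retained, drop = FALSE]))
  y <- unlist(lapply(train, `[[`, "outcome"))
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  z <- zscore(x, mu, sdv)
  retained <- colnames(z)
  corr <- stats::cor(z, use = "pairwise.complete.obs")
  corr[is.na(corr)] <- 0
  diag(corr) <- 1
  clusters <- cluster_features(corr, cutoff = config$corr_cutoff)
  sel <- select_representatives_centralized(clusters, z, y, fdr = config$fdr)
  model <- if (length(sel$selected) > 0)
    fit_logistic_centralized(z[, sel$selected, drop = FALSE], y,
                             tol = config$glore_tol,
                             max_iter = config$max_iter)
  train_pred <- if (!is.null(model)) predict(model, z)
  list(qc = qc, retained = retained, mean = mu, sd = sdv,
       clusters = clusters, selection = sel, model = model,
       threshold = if (!is.null(model)) stats::median(train_pred))
}

train_distributed <- function(train, config) {
  ids <- feature_ids(train[[1]])
  moments <- lapply(train, site_moments)
  qc <- qc_exclude_distributed(moments, config$qc)
  retained <- setdiff(ids, qc$excluded)
  pooled <- pooled_moments(lapply(train, site_moments, ids = retained))
  usable <- is.finite(pooled$global_sd) & pooled$global_sd > 0
  retained <- retained[usable]
  mu <- pooled$global_mean[retained]
  sdv <- pooled$global_sd[retained]
  zsites <- lapply(train, function(s)
    site_dataset(s$site_id, zscore(s$features[, retained, drop = FALSE],
                                   mu, sdv),
                 s$outcome))
  corr <- pooled_correlation(lapply(zsites, site_correlation))
  clusters <- cluster_features(corr, cutoff = config$corr_cutoff)
  votes <- lapply(zsites, site_cluster_vote, clusters = clusters)
  sel <- select_representatives_distributed(
    clusters, votes, vote_threshold = config$vote_threshold)
  model <- if (length(sel$selected) > 0)
    fit_logistic_glore(zsites, sel$selected,
                       tol = config$glore_tol, max_iter = config$max_iter)
  train_pred <- if (!is.null(model))
    unlist(lapply(zsites, function(s) predict(model, s$features)))
  list(qc = qc, retained = retained, mean = mu, sd = sdv,
       clusters = clusters, selection = sel, model = model,
       threshold = if (!is.null(model)) stats::median(train_pred))
}

validate_arm <- function(arm, holdout, config) {
  if (is.null(arm$model)) return(NULL)
  z <- zscore(holdout$features[, arm$retained, drop = FALSE],
              arm$mean, arm$sd)
  keep <- stats::complete.cases(z[, arm$model$feature_ids, drop = FALSE])
  pred <- rep(NA_real_, holdout$n)
  pred[keep] <- predict(arm$model, z[keep, , drop = FALSE])
  pred
}

arm_metrics <- function(pred, holdout, arm, config) {
  keep <- !is.na(pred) & !is.na(holdout$outcome)
  y <- holdout$outcome[keep]
  res <- list(roc = auc_delong(pred[keep], y),
              calibration = tryCatch(calibration_test(pred[keep], y),
                                     error = function(e) NULL))
  if (config$endpoint == "survival_2y" && !is.null(holdout$time_years)) {
    grp <- as.integer(pred[keep] >= arm$threshold)
    res$km <- tryCatch(
      km_and_grho(holdout$time_years[keep], holdout$event[keep], grp,
                  rho = config$rho, horizon = config$horizon),
      error = function(e) NULL)
  }
  res
}

#' Leave-one-cohort-out comparison of centralized and distributed training
#'
#' For each held-out cohort, the remaining cohorts are used for training:
#' quality control, z-scoring, correlation estimation, average-linkage
#' feature clustering, representative selection and multivariate logistic
#' regression are each run centrally (on pooled rows) and/or in the
#' federated fashion (through aggregate messages only), and both models are
#' validated on the held-out cohort. When both arms run, the report also
#' contrasts them: cluster overlap (on the features retained by both QC
#' paths), selected-feature overlap, paired DeLong test, classification
#' discrepancy at the training-median thresholds, and for the survival
#' endpoint Kaplan-Meier risk-group splits with G-rho tests.
#'
#' @param sites list of >= 2 `site_dataset` objects with identical feature
#'   columns.
#' @param config a `workflow_config`.
#' @return An object of class `comparison_report`: one entry per held-out
#'   cohort under `folds`, plus the `config`.
#' @export
run_leave_one_cohort_out <- function(sites, config = workflow_config()) {
  stopifnot(length(sites) >= 2, inherits(config, "workflow_config"))
  prepared <- lapply(sites, prepare_endpoint, config = config)
  for (v in seq_along(prepared)) {
    pooled_y <- unlist(lapply(prepared[-v], `[[`, "outcome"))
    if (length(unique(pooled_y)) < 2)
      stop("training fold holding out '", prepared[[v]]$site_id,
           "' has a single outcome class")
  }
  folds <- lapply(seq_along(prepared), function(v) {
    holdout <- prepared[[v]]
    train <- prepared[-v]
    fold <- list(validation_site = holdout$site_id,
                 n_validation = holdout$n)
    cen <- if (config$mode %in% c("both", "centralized"))
      train_centralized(train, config)
    dis <- if (config$mode %in% c("both", "distributed"))
      train_distributed(train, config)
    if (!is.null(cen)) {
      pred_c <- validate_arm(cen, holdout, config)
      fold$centralized <- c(
        list(selected = cen$selection$selected,
             n_clusters = length(unique(cen$clusters$labels)),
             model = cen$model, threshold = cen$threshold),
        if (!is.null(pred_c)) arm_metrics(pred_c, holdout, cen, config))
    }
    if (!is.null(dis)) {
      pred_d <- validate_arm(dis, holdout, config)
      fold$distributed <- c(
        list(selected = dis$selection$selected,
             n_clusters = length(unique(dis$clusters$labels)),
             model = dis$model, threshold = dis$threshold),
        if (!is.null(pred_d)) arm_metrics(pred_d, holdout, dis, config))
    }
    if (!is.null(cen) && !is.null(dis)) {
      common <- intersect(names(cen$clusters$labels),
                          names(dis$clusters$labels))
      sub <- function(cl) {
        out <- cl
        out$labels <- cl$labels[common]
        out
      }
      fold$cluster_overlap <- cluster_overlap(sub(cen$clusters),
                                              sub(dis$clusters))
      fold$feature_overlap <- suppressWarnings(
        feature_overlap(cen$selection, dis$selection))
      if (!is.null(pred_c) && !is.null(pred_d)) {
        keep <- !is.na(pred_c) & !is.na(pred_d) & !is.na(holdout$outcome)
        fold$delong_p <- delong_paired_test(pred_c[keep], pred_d[keep],
                                            holdout$outcome[keep])
        fold$discrepancy <- classification_discrepancy(
          pred_c[keep], pred_d[keep], cen$threshold, dis$threshold)
      }
    }
    fold
  })
  names(folds) <- vapply(prepared, `[[`, character(1), "site_id")
  structure(list(folds = folds, config = config),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> endpoint %s; %d fold(s)\n",
              x$config$endpoint, length(x$folds)))
  for (f in x$folds) {
    line <- sprintf("  holdout %-10s", f$validation_site)
    if (!is.null(f$centralized$roc))
      line <- paste0(line, sprintf(" AUC_cen %.3f", f$centralized$roc$auc))
    if (!is.null(f$distributed$roc))
      line <- paste0(line, sprintf(" AUC_dis %.3f", f$distributed$roc$auc))
    if (!is.null(f$delong_p))
      line <- paste0(line, sprintf(" DeLong_p %.3f", f$delong_p))
    if (!is.null(f$discrepancy))
      line <- paste0(line, sprintf(" discrepancy %.3f", f$discrepancy))
    cat(line, "\n")
  }
  invisible(x)
}

report_fold_json <- function(f) {
  strip_model <- function(m) if (is.null(m)) NULL else list(
    feature_ids = m$feature_ids, intercept = m$intercept,
    coefficients = as.list(m$coefficients), iterations = m$iterations,
    converged = m$converged, log_likelihood = m$log_likelihood)
  arm_json <- function(a) if (is.null(a)) NULL else list(
    selected = a$selected, n_clusters = a$n_clusters,
    model = strip_model(a$model), threshold = a$threshold,
    auc = a$roc$auc, auc_ci95 = a$roc$ci95,
    calibration_slope = a$calibration$slope,
    calibration_p_vs_one = a$calibration$p_vs_one,
    km = if (!is.null(a$km)) list(grho_chi2 = a$km$grho_chi2,
                                  grho_p = a$km$grho_p,
                                  odds_ratio = a$km$odds_ratio,
                                  or_ci95 = a$km$or_ci95))
  list(validation_site = f$validation_site,
       n_validation = f$n_validation,
       centralized = arm_json(f$centralized),
       distributed = arm_json(f$distributed),
       cluster_overlap = f$cluster_overlap,
       feature_overlap = f$feature_overlap,
       delong_p = f$delong_p,
       discrepancy = f$discrepancy)
}

#' Write a comparison report to JSON
#'
#' @param report a `comparison_report`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(endpoint = report$config$endpoint,
         folds = lapply(unname(report$folds), report_fold_json)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
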