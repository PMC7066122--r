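# Model comparison statistics: DeLong AUC machinery (via pROC), calibration
# slope, classification discrepancy, Kaplan-Meier with the G-rho family of
# weighted log-rank tests (via survival) and the risk-group odds ratio.

check_binary <- function(labels) {
  u <- unique(labels[!is.na(labels)])
  if (!all(u %in% c(0, 1)) || length(u) < 2)
    stop("labels must contain both classes (0 and 1)")
}

#' AUC with DeLong variance and confidence interval
#'
#' The AUC is the probability that a random positive scores above a random
#' negative, ties counted 1/2; its variance comes from the DeLong structural
#' components and the 95% CI is the normal interval clipped to [0, 1].
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels binary labels (0/1).
#' @return An object of class `roc_result`: `auc`, `variance`, `ci95`
#'   (length-2 vector), `n_pos`, `n_neg`.
#' @export
auc_delong <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  check_binary(labels)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(r$auc)
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  if (!is.finite(v) || v < 0) v <- 0
  half <- 1.96 * sqrt(v)
  structure(list(auc = auc, variance = v,
                 ci95 = c(max(0, auc - half), min(1, auc + half)),
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
            class = "roc_result")
}

#' Paired DeLong test comparing two models' AUCs
#'
#' Two-sided test of equal AUCs for two score vectors over the same
#' subjects, using the paired DeLong covariance of the structural
#' components. The statistic depends on the scores only through their
#' ranks, so it is invariant under common strictly monotone transforms.
#' Identical score vectors (or a zero-variance difference) give p = 1.
#'
#' @param scoresA,scoresB score vectors over the same subjects.
#' @param labels binary labels (0/1).
#' @return Two-sided p-value.
#' @export
delong_paired_test <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop("length mismatch")
  check_binary(labels)
  if (identical(rank(scoresA), rank(scoresB))) return(1)
  ra <- pROC::roc(response = labels, predictor = scoresA,
                  levels = c(0, 1), direction = "<", quiet = TRUE)
  rb <- pROC::roc(response = labels, predictor = scoresB,
                  levels = c(0, 1), direction = "<", quiet = TRUE)
  p <- suppressWarnings(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value)
  if (!is.finite(p)) 1 else unname(p)
}

#' Calibration slope test in a validation cohort
#'
#' Regresses the observed outcomes on the model's linear predictor
#' (`logit(prediction)`, the calibration-slope convention) with a univariate
#' logistic model and tests the slope against 1 (Wald, two-sided). A slope
#' near 1 means the predicted risk gradient matches the observed one; the
#' model is flagged well calibrated when p >= 0.05. `scale = "probability"`
#' regresses on the raw probabilities instead (the slope = 1 null is then
#' not the standard calibration hypothesis).
#'
#' @param predictions predicted probabilities, strictly in (0, 1).
#' @param labels observed binary outcomes.
#' @param scale `"logit"` (default) or `"probability"`.
#' @return An object of class `calibration_result`: `slope`, `std_err`,
#'   `p_vs_one`, `well_calibrated`.
#' @export
calibration_test <- function(predictions, labels,
                             scale = c("logit", "probability")) {
  scale <- match.arg(scale)
  if (length(predictions) != length(labels)) stop("length mismatch")
  if (any(predictions <= 0 | predictions >= 1))
    stop("predictions must be strictly inside (0, 1)")
  check_binary(labels)
  z <- if (scale == "logit") stats::qlogis(predictions) else predictions
  if (stats::sd(z) == 0) stop("constant predictions: slope undefined")
  fit <- suppressWarnings(stats::glm(labels ~ z, family = stats::binomial()))
  est <- summary(fit)$coefficients
  slope <- est[2, 1]
  se <- est[2, 2]
  p <- 2 * stats::pnorm(-abs(slope - 1) / se)
  structure(list(slope = slope, std_err = se, p_vs_one = p,
                 well_calibrated = p >= 0.05, scale = scale),
            class = "calibration_result")
}

#' Classification discrepancy between two models
#'
#' Fraction of validation subjects assigned to different classes by two
#' models, each thresholded at its own cutoff (by convention the median
#' prediction of that model on its training cohort; ties at the threshold
#' classify as positive/high-risk).
#'
#' @param predA,predB prediction vectors over the same subjects.
#' @param thresholdA,thresholdB the two models' classification cutoffs.
#' @return Discrepancy fraction in [0, 1].
#' @export
classification_discrepancy <- function(predA, predB, thresholdA, thresholdB) {
  if (length(predA) != length(predB)) stop("length mismatch")
  mean((predA >= thresholdA) != (predB >= thresholdB))
}

#' Kaplan-Meier curves with G-rho test and risk-group odds ratio
#'
#' Product-limit survival estimates per risk group, the Fleming-Harrington
#' G-rho test (weights `S(t)^rho` at each event time; `rho = 0` is the
#' standard log-rank test) on 1 df, and the odds ratio of the 2x2 table of
#' group against event-by-horizon with a Woolf 95% CI (Haldane-Anscombe 0.5
#' correction when any cell is zero). Subjects censored before the horizon
#' without an event have unknown horizon status and are left out of the 2x2
#' table only.
#'
#' @param time follow-up times in years (>= 0).
#' @param event event indicator (1 = event observed).
#' @param group binary risk-group indicator (1 = high risk).
#' @param rho Fleming-Harrington weight exponent (default 0, log-rank).
#' @param horizon horizon in years for the odds-ratio table (default 2).
#' @return An object of class `km_result`: `curves` (per group: `time`,
#'   `surv`, `n_risk`), `grho_chi2`, `grho_p`, `grho_defined`, `odds_ratio`,
#'   `or_ci95`.
#' @export
km_and_grho <- function(time, event, group, rho = 0, horizon = 2) {
  if (any(time < 0)) stop("times must be non-negative")
  if (length(unique(group)) < 2)
    stop("both risk groups must be non-empty")
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_id <- rep(names(sf$strata), sf$strata)
  curves <- lapply(split(seq_along(sf$time), strata_id), function(i)
    list(time = sf$time[i], surv = sf$surv[i], n_risk = sf$n.risk[i]))
  gd <- tryCatch(
    suppressWarnings(
      survival::survdiff(survival::Surv(time, event) ~ group, rho = rho)),
    error = function(e) NULL)
  if (is.null(gd) || sum(event) == 0) {
    chi2 <- NA_real_
    p <- NA_real_
    defined <- FALSE
  } else {
    chi2 <- unname(gd$chisq)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    defined <- TRUE
  }
  status2 <- ifelse(event == 1 & time <= horizon, 1L,
                    ifelse(time >= horizon, 0L, NA_integer_))
  tab <- table(factor(group[!is.na(status2)], levels = sort(unique(group))),
               factor(status2[!is.na(status2)], levels = c(0, 1)))
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  se_log <- sqrt(sum(1 / tab))
  structure(list(curves = curves,
                 grho_chi2 = chi2, grho_p = p, grho_defined = defined,
                 odds_ratio = unname(or),
                 or_ci95 = unname(exp(log(or) + c(-1.96, 1.96) * se_log)),
                 rho = rho, horizon = horizon),
            class = "km_result")
}
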