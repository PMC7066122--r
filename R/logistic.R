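# Newton-Raphson maximum likelihood for logistic regression, written so the
# centralized and federated (GLORE) fitters share one driver. The driver
# only ever sees summed gradient/Hessian/log-likelihood triples, so the
# federated fit is mathematically identical to the pooled fit: the sum of
# per-site sufficient statistics equals the full-data statistics exactly.

SEPARATION_BOUND <- 30  # |beta|_inf beyond this on standardized inputs
                        # indicates (quasi-)separation

`%||%` <- function(a, b) if (is.null(a)) b else a

newton_driver <- function(step_fun, p, tol, max_iter, feature_names) {
  beta <- rep(0, p + 1)
  s <- step_fun(beta)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    qrH <- qr(s$hessian)
    if (qrH$rank < p + 1) {
      piv <- qrH$pivot[seq_len(qrH$rank)]
      stop("singular Hessian; collinear column(s): ",
           paste(c("(Intercept)", feature_names)[-piv], collapse = ", "))
    }
    delta <- solve(qrH, s$gradient)
    step <- 1
    for (h in 0:10) {  # step-halving keeps the log-likelihood non-decreasing
      cand <- beta + step * delta
      s_new <- step_fun(cand)
      if (s_new$log_likelihood >= s$log_likelihood - 1e-12 || h == 10) break
      step <- step / 2
    }
    beta <- cand
    s <- s_new
    iterations <- it
    if (max(abs(beta)) > SEPARATION_BOUND)
      stop("coefficients diverging (|beta| > ", SEPARATION_BOUND,
           "); data are likely separated — no finite MLE")
    if (max(abs(step * delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, iterations = iterations, converged = converged,
       log_likelihood = s$log_likelihood, hessian = s$hessian)
}

make_model <- function(fit, ids, mode, tol, case_counts) {
  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  structure(list(
    feature_ids = ids,
    intercept = unname(fit$beta[1]),
    coefficients = stats::setNames(fit$beta[-1], ids),
    iterations = fit$iterations,
    converged = fit$converged,
    log_likelihood = fit$log_likelihood,
    vcov = vc,
    training_meta = list(mode = mode, tolerance = tol,
                         complete_cases = case_counts)
  ), class = "logistic_model")
}

#' Centralized logistic regression by Newton-Raphson
#'
#' Reference maximum-likelihood fitter: Newton-Raphson from `beta = 0` on
#' the full-data gradient and Hessian, declaring convergence when the
#' L-infinity norm of the coefficient update falls below `tol`. A Newton
#' step that would decrease the log-likelihood is halved (up to 10 times),
#' which does not change the fixed point. Initialization, convergence rule
#' and error handling are shared with [fit_logistic_glore()] so iteration
#' counts are directly comparable.
#'
#' @param x numeric feature matrix (no intercept column; complete cases and
#'   rows with known outcome are used, the rest dropped).
#' @param y binary outcome vector.
#' @param tol L-infinity convergence tolerance on the update (default 1e-8).
#' @param max_iter maximum Newton iterations (default 25).
#' @return An object of class `logistic_model`: `feature_ids`, `intercept`,
#'   `coefficients`, `iterations`, `converged`, `log_likelihood`, the
#'   inverse-Hessian `vcov` (intercept first) and `training_meta`.
#' @export
fit_logistic_centralized <- function(x, y, tol = 1e-8, max_iter = 25) {
  x <- as.matrix(x)
  ids <- colnames(x)
  if (is.null(ids) && ncol(x) > 0) stop("'x' must have column names")
  ids <- ids %||% character(0)
  ds <- site_dataset("pooled", x, y)
  keep <- (if (ncol(x) > 0) stats::complete.cases(x)
           else rep(TRUE, nrow(x))) & !is.na(ds$outcome)
  if (length(unique(ds$outcome[keep])) < 2)
    stop("outcome must contain both classes")
  fit <- newton_driver(
    function(beta) site_newton_step(ds, ids, beta),
    p = length(ids), tol = tol, max_iter = max_iter, feature_names = ids)
  make_model(fit, ids, "centralized", tol,
             stats::setNames(sum(keep), "pooled"))
}

#' Federated logistic regression (GLORE)
#'
#' Fits the pooled maximum-likelihood logistic model without pooling patient
#' rows: at each Newton-Raphson iteration every site returns its local
#' gradient and Hessian at the current coefficients ([site_newton_step()]),
#' the coordinator sums them and takes the Newton step
#' `beta <- beta + (sum H_k)^-1 sum g_k`. Because these sums equal the
#' full-data quantities exactly, the iterates — and hence the fitted
#' coefficients and log-likelihood — coincide with the centralized fit up to
#' floating-point summation order.
#'
#' @param sites list of `site_dataset` objects; a site with zero complete
#'   cases is dropped with a warning.
#' @param ids model feature identifiers, present at every site.
#' @inheritParams fit_logistic_centralized
#' @return A `logistic_model` with `training_meta$mode = "distributed"` and
#'   per-site complete-case counts.
#' @export
fit_logistic_glore <- function(sites, ids, tol = 1e-8, max_iter = 25) {
  usable <- vapply(sites, function(s) {
    sum(stats::complete.cases(s$features[, ids, drop = FALSE]) &
          !is.na(s$outcome))
  }, numeric(1))
  if (any(usable == 0)) {
    warning("dropping site(s) with zero complete cases: ",
            paste(vapply(sites[usable == 0], `[[`, character(1), "site_id"),
                  collapse = ", "))
    sites <- sites[usable > 0]
    usable <- usable[usable > 0]
  }
  if (length(sites) == 0) stop("no site has complete cases")
  pooled_y <- unlist(lapply(sites, function(s) {
    keep <- stats::complete.cases(s$features[, ids, drop = FALSE]) &
      !is.na(s$outcome)
    s$outcome[keep]
  }))
  if (length(unique(pooled_y)) < 2)
    stop("pooled outcome must contain both classes")
  step_fun <- function(beta) {
    msgs <- lapply(sites, site_newton_step, ids = ids, beta = beta)
    Reduce(function(a, m) list(
      gradient = a$gradient + m$gradient,
      hessian = a$hessian + m$hessian,
      log_likelihood = a$log_likelihood + m$log_likelihood
    ), msgs[-1], init = msgs[[1]][c("gradient", "hessian", "log_likelihood")])
  }
  fit <- newton_driver(step_fun, p = length(ids), tol = tol,
                       max_iter = max_iter, feature_names = ids)
  make_model(fit, ids, "distributed", tol,
             stats::setNames(usable,
                             vapply(sites, `[[`, character(1), "site_id")))
}

#' Predicted probabilities from a fitted logistic model
#'
#' @param object a `logistic_model`.
#' @param newdata numeric matrix containing (at least) the model's feature
#'   columns, on the same scale as the training data.
#' @param ... unused.
#' @return Vector of probabilities `plogis(intercept + X beta)` in (0, 1).
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing_cols <- setdiff(object$feature_ids, colnames(newdata))
  if (length(missing_cols) > 0)
    stop("missing model feature(s): ", paste(missing_cols, collapse = ", "))
  eta <- object$intercept +
    drop(newdata[, object$feature_ids, drop = FALSE] %*% object$coefficients)
  stats::plogis(eta)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model [%s]> %d feature(s); logLik %.4f; %d iteration(s)%s\n",
              x$training_meta$mode, length(x$feature_ids),
              x$log_likelihood, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param model a `logistic_model`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    feature_ids = model$feature_ids,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    iterations = model$iterations,
    converged = model$converged,
    log_likelihood = model$log_likelihood,
    training_meta = model$training_meta
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
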