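# Site/coordinator contract: the four message types defined here are the
# only objects that cross the site boundary. Every payload's dimensions
# depend on the feature count only, never on the number of patients (the
# scalar n excepted), which is what makes the exchange privacy-preserving.

g1_skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(NA_real_)
  e1071::skewness(x, type = 1)
}

#' Site-local per-feature moment summary
#'
#' Computes, over non-missing entries per feature, the count, mean, sum of
#' squared deviations from the mean, missing count and sample skewness
#' (g1 = m3 / m2^(3/2), central moments with denominator n). These local
#' statistics are all the coordinator needs for exact global means and
#' standard deviations and for distributed quality control.
#'
#' @param dataset a `site_dataset`.
#' @param ids feature identifiers (default: all features).
#' @return An object of class `moment_summary` with vectors `n_per_feature`,
#'   `mean`, `sum_sq_dev`, `missing_count`, `skewness` (named by feature) and
#'   `skew_undefined`, flagging features with fewer than 3 non-missing values.
#' @export
site_moments <- function(dataset, ids = feature_ids(dataset)) {
  stopifnot(inherits(dataset, "site_dataset"))
  if (dataset$n == 0) stop("dataset is empty")
  x <- dataset$features[, ids, drop = FALSE]
  n_obs <- colSums(!is.na(x))
  mu <- colMeans(x, na.rm = TRUE)
  ssd <- colSums(sweep(x, 2, mu, `-`)^2, na.rm = TRUE)
  skew <- apply(x, 2, g1_skewness)
  structure(list(
    site_id = dataset$site_id,
    n_per_feature = n_obs,
    mean = mu,
    sum_sq_dev = ssd,
    missing_count = dataset$n - n_obs,
    skewness = skew,
    skew_undefined = names(which(n_obs < 3)),
    n = dataset$n,
    schema = "moment_summary/1"
  ), class = "moment_summary")
}

#' Pool site moment summaries into global statistics
#'
#' The weighted mean and the pooled sum of squares
#' `SS = sum_k (SS_k + n_k (mu_k - mu)^2)` reproduce the mean and sample
#' standard deviation of the concatenated data exactly (to floating point),
#' which is what allows distributed z-scoring against global statistics.
#'
#' @param summaries list of `moment_summary` objects over the same features.
#' @return List with vectors `global_mean`, `global_sd`,
#'   `global_missing_fraction` (all named by feature), total counts
#'   `n_per_feature`, and `sd_undefined` flagging features with fewer than
#'   2 non-missing values overall.
#' @export
pooled_moments <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  ids <- names(summaries[[1]]$mean)
  for (s in summaries)
    if (!identical(names(s$mean), ids))
      stop("summaries have inconsistent feature lists")
  n_mat <- do.call(rbind, lapply(summaries, `[[`, "n_per_feature"))
  mu_mat <- do.call(rbind, lapply(summaries, `[[`, "mean"))
  ssd_mat <- do.call(rbind, lapply(summaries, `[[`, "sum_sq_dev"))
  miss_mat <- do.call(rbind, lapply(summaries, `[[`, "missing_count"))
  n_tot <- colSums(n_mat)
  mu <- colSums(n_mat * mu_mat) / n_tot
  ss <- colSums(ssd_mat + n_mat * sweep(mu_mat, 2, mu, `-`)^2)
  sd_undef <- names(which(n_tot < 2))
  sdv <- ifelse(n_tot >= 2, sqrt(ss / pmax(n_tot - 1, 1)), NA_real_)
  names(sdv) <- ids
  list(global_mean = mu,
       global_sd = sdv,
       global_missing_fraction = colSums(miss_mat) / (n_tot + colSums(miss_mat)),
       n_per_feature = n_tot,
       sd_undefined = sd_undef)
}

#' Site-local inter-feature correlation message
#'
#' @param dataset a `site_dataset`.
#' @param ids feature identifiers (default: all features).
#' @param use `"pairwise"` (default) computes each correlation on
#'   pairwise-complete observations, maximizing data use under MCAR
#'   missingness; `"complete"` restricts to rows complete on all features.
#' @return An object of class `correlation_message` with the site's
#'   correlation matrix and the number of patients `n` backing it.
#' @export
site_correlation <- function(dataset, ids = feature_ids(dataset),
                             use = c("pairwise", "complete")) {
  stopifnot(inherits(dataset, "site_dataset"))
  use <- match.arg(use)
  x <- dataset$features[, ids, drop = FALSE]
  if (use == "complete") {
    x <- x[stats::complete.cases(x), , drop = FALSE]
    n <- nrow(x)
    corr <- stats::cor(x)
  } else {
    n <- dataset$n
    corr <- stats::cor(x, use = "pairwise.complete.obs")
  }
  corr[is.na(corr)] <- 0  # degenerate (constant) features carry no signal
  diag(corr) <- 1
  structure(list(site_id = dataset$site_id, corr = corr, n = n,
                 schema = "correlation_message/1"),
            class = "correlation_message")
}

#' Pool site correlation matrices via the Fisher z-transform
#'
#' Each site's coefficients are clipped to +/-(1 - 1e-7), transformed with
#' `atanh`, averaged with weights `n_k - 3` (the inverse variance of the
#' z-transform; plain `n_k` weights available) and back-transformed with
#' `tanh`. The diagonal is forced to exactly 1. Sites with `n <= 3` are
#' excluded with a warning (their z-variance is undefined).
#'
#' @param messages list of `correlation_message` objects of equal dimension.
#' @param weights `"n_minus_3"` (default) or `"n"`.
#' @return Pooled symmetric correlation matrix.
#' @export
pooled_correlation <- function(messages, weights = c("n_minus_3", "n")) {
  weights <- match.arg(weights)
  ns <- vapply(messages, `[[`, numeric(1), "n")
  drop <- ns <= 3
  if (any(drop)) {
    warning("excluding site(s) with n <= 3 from correlation pooling: ",
            paste(vapply(messages[drop], `[[`, character(1), "site_id"),
                  collapse = ", "))
    messages <- messages[!drop]
    ns <- ns[!drop]
  }
  if (length(messages) == 0) stop("no site has n >= 4")
  d <- dim(messages[[1]]$corr)
  for (m in messages)
    if (!identical(dim(m$corr), d))
      stop("correlation matrices have inconsistent dimensions")
  w <- if (weights == "n_minus_3") ns - 3 else ns
  lim <- 1 - 1e-7
  zsum <- 0
  for (k in seq_along(messages))
    zsum <- zsum + w[k] * atanh(pmin(pmax(messages[[k]]$corr, -lim), lim))
  pooled <- tanh(zsum / sum(w))
  dimnames(pooled) <- dimnames(messages[[1]]$corr)
  diag(pooled) <- 1
  pooled
}

#' Site-local per-cluster AUC vote
#'
#' For each cluster, the site evaluates every member feature's univariate
#' discriminative performance (AUC of a univariate logistic model, see
#' [univariate_auc()]) on its local complete cases and nominates the best
#' one; AUC ties are broken by the lexicographically smallest feature id.
#'
#' @param dataset a `site_dataset`.
#' @param clusters a `cluster_assignment` over features present in the site.
#' @return An object of class `cluster_vote_message`: the site id, the number
#'   of patients with known outcome `n` (the site's voting weight), and a
#'   data frame `votes` with one row per cluster (`cluster`, `feature`,
#'   `auc`).
#' @export
site_cluster_vote <- function(dataset, clusters) {
  stopifnot(inherits(dataset, "site_dataset"),
            inherits(clusters, "cluster_assignment"))
  ids <- names(clusters$labels)
  bad <- setdiff(ids, feature_ids(dataset))
  if (length(bad) > 0)
    stop("clustered feature(s) absent from site: ", paste(bad, collapse = ", "))
  y <- dataset$outcome
  votes <- lapply(sort(unique(clusters$labels)), function(cl) {
    members <- sort(ids[clusters$labels == cl])
    aucs <- vapply(members, function(f)
      univariate_auc(dataset$features[, f], y)$auc, numeric(1))
    best <- members[which.max(aucs)]  # which.max takes the first = smallest id
    data.frame(cluster = cl, feature = best, auc = unname(aucs[best]))
  })
  structure(list(site_id = dataset$site_id,
                 n = sum(!is.na(y)),
                 votes = do.call(rbind, votes),
                 schema = "cluster_vote_message/1"),
            class = "cluster_vote_message")
}

#' Site-local Newton-Raphson contribution for logistic regression
#'
#' At the current coefficient vector `beta` (intercept first), the site
#' computes on its complete cases, with design matrix `X` (column of ones
#' prepended) and fitted probabilities `p = plogis(X beta)`:
#' gradient `X'(y - p)`, Hessian `X' diag(p(1-p)) X` and the Bernoulli
#' log-likelihood. Sites are additive: the sums of these messages equal the
#' same quantities on the concatenated data, which is why the federated fit
#' reproduces the pooled maximum likelihood estimate exactly.
#'
#' @param dataset a `site_dataset`.
#' @param ids model feature identifiers.
#' @param beta numeric vector of length `length(ids) + 1` (intercept first).
#' @return An object of class `newton_message` with `gradient`, `hessian`,
#'   `log_likelihood` and the complete-case count `n`.
#' @export
site_newton_step <- function(dataset, ids, beta) {
  stopifnot(inherits(dataset, "site_dataset"))
  x <- if (length(ids) > 0) dataset$features[, ids, drop = FALSE]
       else dataset$features[, 0, drop = FALSE]
  keep <- (if (length(ids) > 0) stats::complete.cases(x)
           else rep(TRUE, dataset$n)) & !is.na(dataset$outcome)
  x <- x[keep, , drop = FALSE]
  y <- dataset$outcome[keep]
  if (nrow(x) == 0) stop("site '", dataset$site_id, "' has zero complete cases")
  if (any(!is.finite(x))) stop("non-finite feature values in model columns")
  if (length(beta) != length(ids) + 1)
    stop("'beta' must have length length(ids) + 1 (intercept first)")
  X <- cbind(`(Intercept)` = 1, x)
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  structure(list(
    site_id = dataset$site_id,
    gradient = drop(crossprod(X, y - p)),
    hessian = crossprod(X * sqrt(w)),
    log_likelihood = sum(y * eta -
                           ifelse(eta > 0, eta + log1p(exp(-eta)),
                                  log1p(exp(eta)))),
    n = nrow(x),
    schema = "newton_message/1"
  ), class = "newton_message")
}

#' Serialize a federation message to JSON
#'
#' Produces the wire format of the site-to-coordinator messages: named
#' numeric arrays (matrices row-major as nested arrays) plus the schema tag.
#' Used by the privacy audit, which inspects serialized payloads and checks
#' that no array has a patient-indexed axis.
#'
#' @param msg a `moment_summary`, `correlation_message`,
#'   `cluster_vote_message` or `newton_message`.
#' @return A JSON string.
#' @export
serialize_message <- function(msg) {
  if (!inherits(msg, c("moment_summary", "correlation_message",
                       "cluster_vote_message", "newton_message")))
    stop("not a federation message")
  jsonlite::toJSON(unclass(msg), auto_unbox = TRUE, digits = NA, na = "null")
}
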