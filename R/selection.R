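#' Z-score a feature matrix against supplied statistics
#'
#' Standardizes each column as `(x - mean) / sd`; missing entries stay
#' missing. In the distributed workflow the statistics are the global ones
#' from [pooled_moments()], so each site standardizes against the federation
#' rather than itself. Constant features (`sd` zero or undefined) cannot be
#' standardized and are dropped with a warning.
#'
#' @param x numeric matrix with named columns.
#' @param mean,sd named numeric vectors covering the columns of `x`.
#' @return The standardized matrix, possibly with fewer columns.
#' @export
zscore <- function(x, mean, sd) {
  ids <- colnames(x)
  mean <- mean[ids]
  sd <- sd[ids]
  bad <- !is.finite(sd) | sd == 0
  if (any(bad)) {
    warning("dropping constant feature(s): ",
            paste(ids[bad], collapse = ", "))
    x <- x[, !bad, drop = FALSE]
    mean <- mean[!bad]
    sd <- sd[!bad]
  }
  sweep(sweep(x, 2, mean, `-`), 2, sd, `/`)
}

#' Cluster features by correlation with average-linkage agglomeration
#'
#' Features are clustered on the distance `1 - |r|` (optionally the signed
#' `1 - r`) with average linkage; flat clusters are obtained by cutting the
#' dendrogram at height `1 - cutoff`, i.e. features stay merged while their
#' average correlation magnitude is at least `cutoff`.
#'
#' @param corr symmetric correlation matrix with named rows/columns, unit
#'   diagonal, entries in [-1, 1].
#' @param cutoff correlation cutoff (default 0.6).
#' @param signed if `TRUE`, use the signed distance `1 - r`, separating
#'   anti-correlated features.
#' @return An object of class `cluster_assignment`: `labels` (named integer
#'   vector, clusters 1..C), and the linkage record `merge`/`height` from
#'   [stats::hclust()].
#' @export
cluster_features <- function(corr, cutoff = 0.6, signed = FALSE) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("'corr' must be a square matrix")
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("'corr' must be symmetric")
  if (any(abs(corr) > 1 + 1e-8))
    stop("correlation entries must lie in [-1, 1]")
  ids <- colnames(corr)
  if (is.null(ids)) stop("'corr' must have column names")
  if (nrow(corr) == 1) {
    labels <- stats::setNames(1L, ids)
    return(structure(list(labels = labels, merge = NULL, height = NULL,
                          cutoff = cutoff, signed = signed),
                     class = "cluster_assignment"))
  }
  d <- if (signed) 1 - corr else 1 - abs(corr)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- stats::cutree(hc, h = 1 - cutoff)
  structure(list(labels = labels, merge = hc$merge, height = hc$height,
                 cutoff = cutoff, signed = signed),
            class = "cluster_assignment")
}

#' Univariate discriminative performance of one feature
#'
#' Fits a univariate logistic regression of the outcome on the feature
#' (complete cases) and reports the AUC of its predictions together with the
#' Wald p-value of the slope. Because the logistic link is monotone, the
#' model's AUC equals `max(a, 1 - a)` where `a` is the rank-statistic AUC of
#' the raw feature with ties counted 1/2.
#'
#' @param x numeric feature vector.
#' @param y binary outcome vector (0/1; `NA` allowed, dropped).
#' @return List with `auc` (in [0.5, 1]), `p_value` (Wald p of the slope;
#'   1 for a constant feature) and `direction` (+1 if higher values indicate
#'   the positive class, -1 otherwise).
#' @export
univariate_auc <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(unique(y)) < 2)
    stop("outcome must contain both classes")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(x)
  a <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (stats::sd(x) == 0)
    return(list(auc = 0.5, p_value = 1, direction = 1))
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  coefs <- summary(fit)$coefficients
  p <- if (nrow(coefs) < 2 || is.na(coefs[2, 4])) 1 else coefs[2, 4]
  list(auc = max(a, 1 - a), p_value = p, direction = if (a >= 0.5) 1 else -1)
}

#' Centralized per-cluster representative selection
#'
#' Univariate AUCs and Wald p-values are computed for every retained feature
#' on the pooled data; Benjamini-Hochberg adjustment is applied across all
#' retained features. Each cluster's candidate is its highest-AUC feature
#' (ties to the lexicographically smallest id); the candidate enters the
#' selection iff its adjusted p-value is below `fdr`.
#'
#' @param clusters a `cluster_assignment` over the retained features.
#' @param x pooled feature matrix (rows = all patients of all training sites).
#' @param y pooled binary outcome.
#' @param fdr false discovery rate gate (default 0.05).
#' @return An object of class `selection_result`: `selected` (character
#'   vector ordered by cluster label), `per_cluster` (data frame with the
#'   candidate, its AUC, raw and adjusted p, and selection flag) and
#'   `mode = "centralized"`.
#' @export
select_representatives_centralized <- function(clusters, x, y, fdr = 0.05) {
  stopifnot(inherits(clusters, "cluster_assignment"))
  ids <- names(clusters$labels)
  stats_list <- lapply(ids, function(f) univariate_auc(x[, f], y))
  auc <- vapply(stats_list, `[[`, numeric(1), "auc")
  pval <- vapply(stats_list, `[[`, numeric(1), "p_value")
  names(auc) <- names(pval) <- ids
  padj <- stats::p.adjust(pval, method = "BH")
  per_cluster <- do.call(rbind, lapply(sort(unique(clusters$labels)),
                                       function(cl) {
    members <- sort(ids[clusters$labels == cl])
    best <- members[which.max(auc[members])]
    data.frame(cluster = cl, feature = best, auc = unname(auc[best]),
               p_value = unname(pval[best]), p_adjusted = unname(padj[best]),
               selected = unname(padj[best]) < fdr)
  }))
  structure(list(selected = per_cluster$feature[per_cluster$selected],
                 per_cluster = per_cluster,
                 mode = "centralized", fdr = fdr),
            class = "selection_result")
}

#' Distributed representative selection by weighted voting
#'
#' Each site nominates its best feature per cluster ([site_cluster_vote()]).
#' A feature's vote weight is the summed cohort size of the sites nominating
#' it, divided by the total cohort size; it is selected iff its weight
#' reaches `vote_threshold` (non-strict). There is no FDR gate on this path:
#' the vote threshold is its only filter.
#'
#' @param clusters a `cluster_assignment` (used to validate vote consistency).
#' @param votes list of `cluster_vote_message` objects.
#' @param vote_threshold minimum weighted selection rate (default 0.8).
#' @return An object of class `selection_result` with `mode = "distributed"`;
#'   `per_cluster` lists, per cluster, the leading candidate and its weight.
#' @export
select_representatives_distributed <- function(clusters, votes,
                                               vote_threshold = 0.8) {
  stopifnot(inherits(clusters, "cluster_assignment"), length(votes) >= 1)
  ids <- names(clusters$labels)
  for (v in votes) {
    ok <- clusters$labels[v$votes$feature] == v$votes$cluster
    if (any(is.na(ok)) || !all(ok))
      stop("site '", v$site_id,
           "' voted for features outside the claimed cluster")
  }
  total_w <- sum(vapply(votes, `[[`, numeric(1), "n"))
  per_cluster <- do.call(rbind, lapply(sort(unique(clusters$labels)),
                                       function(cl) {
    cand <- do.call(rbind, lapply(votes, function(v) {
      row <- v$votes[v$votes$cluster == cl, , drop = FALSE]
      if (nrow(row) == 0) return(NULL)
      data.frame(feature = row$feature, w = v$n)
    }))
    wt <- tapply(cand$w, cand$feature, sum) / total_w
    wt <- wt[order(-wt, names(wt))]  # weight ties: smallest feature id leads
    lead <- names(wt)[1]
    data.frame(cluster = cl, feature = lead, weight = unname(wt[1]),
               selected = unname(wt[1]) >= vote_threshold)
  }))
  structure(list(selected = per_cluster$feature[per_cluster$selected],
                 per_cluster = per_cluster,
                 mode = "distributed", vote_threshold = vote_threshold),
            class = "selection_result")
}

#' Agreement between two clusterings of the same features
#'
#' For each cluster of the first (reference, typically centralized)
#' assignment, the largest subcluster under the second (typically
#' distributed) assignment is found — the most common second-assignment
#' label among its members. The overlap is the summed size of these largest
#' subclusters divided by the total feature count. Note that with all
#' singleton reference clusters the overlap is 1 regardless of the second
#' assignment; the metric rewards the reference clusters being preserved as
#' blocks.
#'
#' @param central,distributed `cluster_assignment` objects over the same
#'   feature universe.
#' @return Overlap fraction in [0, 1].
#' @export
cluster_overlap <- function(central, distributed) {
  stopifnot(inherits(central, "cluster_assignment"),
            inherits(distributed, "cluster_assignment"))
  ids <- names(central$labels)
  if (!setequal(ids, names(distributed$labels)))
    stop("clusterings cover different feature sets")
  dl <- distributed$labels[ids]
  covered <- sum(vapply(unique(central$labels), function(cl) {
    max(table(dl[central$labels == cl]))
  }, numeric(1)))
  covered / length(ids)
}

#' Overlap between two feature selections
#'
#' @param selA,selB `selection_result` objects (or character vectors).
#' @return List with `jaccard` (|A n B| / |A u B|), `frac_of_A`, `frac_of_B`
#'   and the intersection size `n_common`. Two empty selections overlap
#'   fully by convention (with a warning).
#' @export
feature_overlap <- function(selA, selB) {
  a <- if (inherits(selA, "selection_result")) selA$selected else selA
  b <- if (inherits(selB, "selection_result")) selB$selected else selB
  if (length(a) == 0 && length(b) == 0) {
    warning("both selections are empty; overlap defined as 1")
    return(list(jaccard = 1, frac_of_A = 1, frac_of_B = 1, n_common = 0L))
  }
  common <- length(intersect(a, b))
  list(jaccard = common / length(union(a, b)),
       frac_of_A = if (length(a)) common / length(a) else NA_real_,
       frac_of_B = if (length(b)) common / length(b) else NA_real_,
       n_common = as.integer(common))
}

#' Serialize a selection result to JSON
#'
#' @param sel a `selection_result`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(list(mode = sel$mode, selected = sel$selected,
                            per_cluster = sel$per_cluster),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
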