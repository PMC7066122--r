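test_that("z-scoring against pooled statistics standardizes the concatenation", {
  sites <- make_sites(K = 3, n = c(60, 90, 75), seed = 23,
                      site_mean_shift_sd = 0.5)
  ids <- colnames(sites[[1]]$features)
  pm <- pooled_moments(lapply(sites, site_moments))
  z <- do.call(rbind, lapply(sites, function(s)
    zscore(s$features, pm$global_mean, pm$global_sd)))
  expect_equal(unname(colMeans(z)), rep(0, length(ids)), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, length(ids)), tolerance = 1e-12)

  # x = mean maps to 0
  expect_equal(unname(zscore(cbind(a = c(2, 2)), c(a = 2), c(a = 3))[, 1]),
               c(0, 0))
  # constant feature is flagged and dropped
  expect_warning(
    out <- zscore(cbind(a = 1:4, b = rep(1, 4)), c(a = 2.5, b = 1),
                  c(a = sd(1:4), b = 0)),
    "constant")
  expect_identical(colnames(out), "a")
})

test_that("average-linkage clustering cuts the dendrogram at 1 - cutoff", {
  mk_corr <- function(m, ids) {
    dimnames(m) <- list(ids, ids)
    m
  }
  # one merge above the cutoff
  r <- mk_corr(matrix(c(1, .9, 0, .9, 1, 0, 0, 0, 1), 3), c("a", "b", "c"))
  cl <- cluster_features(r, cutoff = 0.6)
  expect_equal(unname(cl$labels["a"]), unname(cl$labels["b"]))
  expect_false(cl$labels["c"] == cl$labels["a"])

  # identity matrix: all singletons
  ident <- mk_corr(diag(4), paste0("f", 1:4))
  expect_equal(length(unique(cluster_features(ident)$labels)), 4)

  # two tight pairs, weak across: two clusters of two (average linkage by hand:
  # pairs merge at d = 0.3 <= 0.4; cross-merge at mean d = 0.9 > 0.4)
  r4 <- mk_corr(matrix(0.1, 4, 4), paste0("f", 1:4))
  diag(r4) <- 1
  r4[1, 2] <- r4[2, 1] <- 0.7
  r4[3, 4] <- r4[4, 3] <- 0.7
  cl4 <- cluster_features(r4, cutoff = 0.6)
  expect_equal(unname(cl4$labels), c(1, 1, 2, 2))

  # anti-correlated features co-cluster on |r| but split in signed mode
  ra <- mk_corr(matrix(c(1, -.9, -.9, 1), 2), c("a", "b"))
  expect_equal(length(unique(cluster_features(ra)$labels)), 1)
  expect_equal(length(unique(cluster_features(ra, signed = TRUE)$labels)), 2)

  expect_error(cluster_features(mk_corr(matrix(c(1, .2, .5, 1), 2),
                                        c("a", "b"))), "symmetric")
})

test_that("clustering is invariant to feature order up to label permutation", {
  sites <- make_sites(K = 1, n = 400, rho = 0.75, seed = 29)
  corr <- cor(sites[[1]]$features)
  perm <- sample(ncol(corr))
  cl1 <- cluster_features(corr)
  cl2 <- cluster_features(corr[perm, perm])
  ids <- colnames(corr)
  same1 <- outer(cl1$labels[ids], cl1$labels[ids], `==`)
  same2 <- outer(cl2$labels[ids], cl2$labels[ids], `==`)
  expect_identical(same1, same2)
})

test_that("univariate AUC equals the rank statistic folded above one half", {
  expect_equal(univariate_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(univariate_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(univariate_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  # a feature predicting the negative class folds to the same AUC
  expect_equal(univariate_auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(univariate_auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$direction, -1)

  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(40)
    y <- rbinom(40, 1, plogis(x))
    if (length(unique(y)) < 2) next
    a <- brute_auc(x, y)
    expect_equal(univariate_auc(x, y)$auc, max(a, 1 - a))
  }
  expect_error(univariate_auc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("centralized representatives take the max-AUC feature behind a BH gate", {
  set.seed(44)
  n <- 300
  strong <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * strong))
  x <- cbind(f1 = strong + rnorm(n, sd = 0.4),
             f2 = strong + rnorm(n, sd = 0.1),  # best proxy in cluster 1
             f3 = rnorm(n), f4 = rnorm(n))
  corr <- cor(x)
  clusters <- cluster_features(corr, cutoff = 0.6)
  sel <- select_representatives_centralized(clusters, x, y, fdr = 0.05)
  expect_true("f2" %in% sel$selected)          # highest AUC in its cluster
  expect_false(any(c("f1") %in% sel$selected)) # one winner per cluster
  noise_rows <- sel$per_cluster[sel$per_cluster$feature %in% c("f3", "f4"), ]
  expect_true(all(!noise_rows$selected | noise_rows$p_adjusted < 0.05))

  # null outcome: FDR control keeps expected selections near zero
  y0 <- rbinom(n, 1, 0.5)
  sel0 <- select_representatives_centralized(clusters, x, y0, fdr = 0.05)
  expect_lte(length(sel0$selected), 1)

  # AUC ties break to the lexicographically smallest id
  xt <- cbind(b = c(1, 2, 3, 4), a = c(1, 2, 3, 4))
  ct <- cluster_features(cor(xt), cutoff = 0.6)
  st <- select_representatives_centralized(ct, xt, c(0, 0, 1, 1))
  expect_identical(st$per_cluster$feature, "a")
})

test_that("distributed selection applies cohort-size-weighted voting", {
  labels <- c(f1 = 1L, f2 = 1L)
  clusters <- structure(list(labels = labels), class = "cluster_assignment")
  vote <- function(id, n, feat)
    structure(list(site_id = id, n = n,
                   votes = data.frame(cluster = 1L, feature = feat,
                                      auc = 0.7)),
              class = "cluster_vote_message")
  # cohort sizes 206, 441, 100, 141; three of four vote f1:
  # weight 747/888 = 0.841 >= 0.8
  votes <- list(vote("a", 206, "f1"), vote("b", 441, "f1"),
                vote("c", 100, "f1"), vote("d", 141, "f2"))
  sel <- select_representatives_distributed(clusters, votes)
  expect_identical(sel$selected, "f1")
  expect_equal(sel$per_cluster$weight, 747 / 888)

  # unanimity selects with weight 1
  un <- select_representatives_distributed(clusters,
                                           list(vote("a", 50, "f1"),
                                                vote("b", 70, "f1")))
  expect_equal(un$per_cluster$weight, 1)
  expect_identical(un$selected, "f1")

  # an even split selects nothing at the 80% threshold
  split <- select_representatives_distributed(clusters,
                                              list(vote("a", 50, "f1"),
                                                   vote("b", 50, "f2")))
  expect_identical(split$selected, character(0))

  # monotone in the threshold: raising it never adds features
  lo <- select_representatives_distributed(clusters, votes,
                                           vote_threshold = 0.5)
  hi <- select_representatives_distributed(clusters, votes,
                                           vote_threshold = 0.9)
  expect_true(all(hi$selected %in% lo$selected))

  # votes outside the claimed cluster are rejected
  bad <- list(vote("a", 50, "f1"),
              structure(list(site_id = "b", n = 50,
                             votes = data.frame(cluster = 2L, feature = "f1",
                                                auc = 0.7)),
                        class = "cluster_vote_message"))
  expect_error(select_representatives_distributed(clusters, bad),
               "outside the claimed cluster")
})

test_that("with one site, distributed selection is per-cluster max AUC, no FDR gate", {
  s <- make_sites(K = 1, n = 250, rho = 0.7, seed = 37)[[1]]
  corr <- cor(s$features)
  clusters <- cluster_features(corr)
  votes <- list(site_cluster_vote(s, clusters))
  sel <- select_representatives_distributed(clusters, votes)
  # every cluster winner is selected with weight 1
  expect_equal(sel$per_cluster$weight, rep(1, nrow(sel$per_cluster)))
  expect_equal(length(sel$selected), length(unique(clusters$labels)))
  # and each winner is the local max-AUC member of its cluster
  for (i in seq_len(nrow(sel$per_cluster))) {
    cl <- sel$per_cluster$cluster[i]
    members <- names(clusters$labels)[clusters$labels == cl]
    aucs <- vapply(members, function(f)
      univariate_auc(s$features[, f], s$outcome)$auc, numeric(1))
    expect_equal(max(aucs), unname(aucs[sel$per_cluster$feature[i]]))
  }
})

test_that("cluster overlap follows its largest-subcluster definition", {
  mk <- function(labels) structure(list(labels = labels),
                                   class = "cluster_assignment")
  ids <- paste0("f", 1:4)
  same <- mk(setNames(c(1L, 1L, 2L, 2L), ids))
  expect_equal(cluster_overlap(same, same), 1)

  # all singleton reference clusters: overlap 1 by construction
  singles <- mk(setNames(1:4, ids))
  lumped <- mk(setNames(rep(1L, 4), ids))
  expect_equal(cluster_overlap(singles, lumped), 1)

  # one reference cluster split 2/1/1: overlap 2/4
  whole <- mk(setNames(rep(1L, 4), ids))
  split <- mk(setNames(c(1L, 1L, 2L, 3L), ids))
  expect_equal(cluster_overlap(whole, split), 0.5)

  expect_error(cluster_overlap(whole, mk(setNames(1L, "f9"))),
               "different feature sets")
})

test_that("feature overlap reports Jaccard and containment fractions", {
  ov <- feature_overlap(c("f1", "f2", "f3"), c("f2", "f3", "f4"))
  expect_equal(ov$jaccard, 0.5)
  expect_equal(ov$frac_of_A, 2 / 3)
  expect_equal(ov$n_common, 2L)
  expect_equal(feature_overlap(c("a"), c("a"))$jaccard, 1)
  expect_equal(feature_overlap(c("a"), c("b"))$jaccard, 0)
  expect_warning(empty <- feature_overlap(character(0), character(0)),
                 "empty")
  expect_equal(empty$jaccard, 1)
})
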