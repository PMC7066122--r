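# Fixture builders and independent oracles shared across the suite.

# A small federation with block-correlated features and a known outcome model.
make_sites <- function(K = 3, n = rep(150, K), num_clusters = 4,
                       features_per_cluster = 2, rho = 0.6,
                       beta = c(f001 = 0.9, f003 = -0.7), seed = 42, ...) {
  cfg <- generator_config(num_sites = K, patients_per_site = n,
                          num_clusters = num_clusters,
                          features_per_cluster = features_per_cluster,
                          within_cluster_corr = rho,
                          true_coefficients = beta, seed = seed, ...)
  generate_federation(cfg)
}

# Split fixed (x, y) rows into K site_datasets at random.
random_partition <- function(x, y, K, seed = 1) {
  set.seed(seed)
  grp <- sample(rep_len(seq_len(K), nrow(x)))
  lapply(seq_len(K), function(k)
    site_dataset(paste0("part", k), x[grp == k, , drop = FALSE], y[grp == k]))
}

# Brute-force AUC: enumerate all positive-negative pairs, ties count 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Log-rank statistic computed directly from its definition (no censoring
# assumed handled through the risk sets).
logrank_oracle <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n_1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d_1 <- sum(time == t & event == 1 & group == 1)
    O <- O + d_1
    E <- E + d * n_1 / n_tot
    if (n_tot > 1)
      V <- V + d * (n_1 / n_tot) * (1 - n_1 / n_tot) * (n_tot - d) / (n_tot - 1)
  }
  (O - E)^2 / V
}

# Moments of concatenated raw data, the oracle for pooled_moments.
concat_moments <- function(sites, ids) {
  x <- do.call(rbind, lapply(sites, function(s) s$features[, ids, drop = FALSE]))
  list(mean = colMeans(x, na.rm = TRUE),
       sd = apply(x, 2, stats::sd, na.rm = TRUE))
}
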