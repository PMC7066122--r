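test_that("centralized Newton fit matches closed forms and a grid-search oracle", {
  # intercept-only model: MLE is the logit of the prevalence
  x <- matrix(numeric(0), nrow = 100, ncol = 0)
  y <- rep(c(1, 1, 1, 0), 25)
  fit <- fit_logistic_centralized(x, y)
  expect_equal(fit$intercept, log(3), tolerance = 1e-8)

  # two-point design with 10% label noise: grid-search maximum likelihood
  x2 <- cbind(x = rep(c(-1, 1), each = 50))
  y2 <- c(rep(0, 45), rep(1, 5), rep(1, 45), rep(0, 5))
  fit2 <- fit_logistic_centralized(x2, y2)
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x2[, 1]
    sum(y2 * eta - log1p(exp(eta)))
  }
  grid <- expand.grid(b0 = seq(-1, 1, by = 0.001),
                      b1 = seq(1.5, 3, by = 0.001))
  best <- grid[which.max(mapply(loglik, grid$b0, grid$b1)), ]
  expect_equal(fit2$intercept, best$b0, tolerance = 1e-3)
  expect_equal(unname(fit2$coefficients), best$b1, tolerance = 1e-3)
  # the exact MLE of this saturated design is (0, logit(0.9))
  expect_equal(fit2$intercept, 0, tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients), qlogis(0.9), tolerance = 1e-8)
})

test_that("centralized fit agrees with glm on realistic data", {
  sites <- make_sites(K = 1, n = 300, seed = 51)
  x <- sites[[1]]$features[, c("f001", "f003", "f005", "f007")]
  y <- sites[[1]]$outcome
  fit <- fit_logistic_centralized(x, y)
  ref <- glm(y ~ x, family = binomial)
  expect_equal(c(fit$intercept, unname(fit$coefficients)),
               unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("degenerate designs raise informative errors", {
  set.seed(3)
  # perfectly separated data: no finite MLE
  xs <- cbind(x = c(-(1:20), 1:20) / 20)
  ys <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic_centralized(xs, ys), "separated")
  # collinear columns: singular Hessian
  z <- rnorm(50)
  xc <- cbind(a = z, b = 2 * z)
  yc <- rbinom(50, 1, plogis(z))
  expect_error(fit_logistic_centralized(xc, yc), "singular Hessian")
  # single-class outcome
  expect_error(fit_logistic_centralized(cbind(a = rnorm(10)), rep(1, 10)),
               "both classes")
})

test_that("GLORE reproduces the centralized fit on arbitrary partitions", {
  sites <- make_sites(K = 1, n = 400, num_clusters = 5,
                      features_per_cluster = 2, rho = 0.4, seed = 61)
  full <- sites[[1]]
  ids <- sprintf("f%03d", c(1, 3, 5, 7, 9))
  cen <- fit_logistic_centralized(full$features[, ids], full$outcome)

  # single site: exact reduction
  one <- fit_logistic_glore(list(full), ids)
  expect_lt(sum(abs(c(one$intercept, one$coefficients) -
                      c(cen$intercept, cen$coefficients))), 1e-12)

  # property: random K-way partitions agree to well under 1e-7
  for (trial in 1:10) {
    K <- sample(2:5, 1)
    parts <- random_partition(full$features, full$outcome, K, seed = trial)
    glore <- fit_logistic_glore(parts, ids)
    expect_lt(sum(abs(c(glore$intercept, glore$coefficients) -
                        c(cen$intercept, cen$coefficients))), 1e-10)
    expect_equal(glore$log_likelihood, cen$log_likelihood, tolerance = 1e-10)
    expect_lt(glore$iterations, 10)
  }
})

test_that("GLORE drops empty sites with a warning and needs both classes", {
  sites <- make_sites(K = 2, n = c(100, 100), seed = 71)
  hollow <- sites[[2]]
  hollow$features[, "f001"] <- NA_real_
  expect_warning(fit <- fit_logistic_glore(list(sites[[1]], hollow),
                                           c("f001", "f002")),
                 "zero complete cases")
  solo <- fit_logistic_glore(list(sites[[1]]), c("f001", "f002"))
  expect_equal(fit$coefficients, solo$coefficients)

  oneclass <- lapply(sites, function(s) {
    s$outcome[] <- 1L
    s
  })
  expect_error(fit_logistic_glore(oneclass, "f001"), "both classes")
})

test_that("predictions follow the logistic link and the final Newton state", {
  sites <- make_sites(K = 1, n = 150, seed = 81)
  ds <- sites[[1]]
  ids <- c("f001", "f003")
  fit <- fit_logistic_centralized(ds$features[, ids], ds$outcome)

  # all-zero model predicts one half
  null_model <- fit
  null_model$intercept <- 0
  null_model$coefficients[] <- 0
  expect_equal(predict(null_model, ds$features),
               rep(0.5, ds$n), ignore_attr = TRUE)

  # monotone in a positive-coefficient feature
  pos_id <- names(which(fit$coefficients > 0))[1]
  bumped <- ds$features
  bumped[, pos_id] <- bumped[, pos_id] + 1
  expect_true(all(predict(fit, bumped) >= predict(fit, ds$features)))

  # training predictions equal the probabilities of the final Newton step
  msg <- site_newton_step(ds, ids, c(fit$intercept, fit$coefficients))
  eta <- fit$intercept + drop(ds$features[, ids] %*% fit$coefficients)
  expect_equal(msg$log_likelihood,
               sum(ds$outcome * log(plogis(eta)) +
                     (1 - ds$outcome) * log(1 - plogis(eta))))
  expect_equal(predict(fit, ds$features), plogis(eta))

  expect_error(predict(fit, ds$features[, "f001", drop = FALSE]),
               "missing model feature")
})

test_that("fitted coefficients recover the generator truth within 3 SE", {
  # moderate simulation here; the full 200-replicate study runs in the
  # acceptance suite
  truth <- c(0.8, -0.6)   # f001, f003 effects; intercept 0
  hits <- 0L
  total <- 0L
  for (seed in 1:25) {
    sites <- make_sites(K = 2, n = c(150, 150), num_clusters = 4,
                        features_per_cluster = 1, rho = 0.3,
                        beta = c(f001 = truth[1], f003 = truth[2]),
                        seed = seed)
    fit <- fit_logistic_glore(sites, sprintf("f%03d", 1:4))
    se <- sqrt(diag(fit$vcov))
    est <- c(fit$intercept, fit$coefficients)
    tr <- c(0, truth[1], 0, truth[2], 0)
    hits <- hits + sum(abs(est - tr) <= 3 * se)
    total <- total + length(tr)
  }
  expect_gte(hits / total, 0.95)
})

test_that("model JSON serialization round-trips the coefficients", {
  sites <- make_sites(K = 1, n = 120, seed = 91)
  fit <- fit_logistic_centralized(sites[[1]]$features[, c("f001", "f002")],
                                  sites[[1]]$outcome)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(unlist(back$coefficients), fit$coefficients)
  expect_identical(back$training_meta$mode, "centralized")
})
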