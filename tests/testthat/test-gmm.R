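test_that("standardization gives population z-scores and is invertible", {
  expect_equal(standardize_features(matrix(c(1, 3), ncol = 1))$x,
               matrix(c(-1, 1), ncol = 1)) # population sd = 1
  set.seed(51)
  X <- matrix(rnorm(600, c(5, -2, 0), c(2, 0.1, 7)), 200, 3, byrow = TRUE)
  std <- standardize_features(X)
  expect_equal(colMeans(std$x), rep(0, 3), tolerance = 1e-10)
  expect_equal(sqrt(colMeans(sweep(std$x, 2, colMeans(std$x))^2)),
               rep(1, 3), tolerance = 1e-10)
  back <- sweep(sweep(std$x, 2, std$scale, "*"), 2, std$center, "+")
  expect_equal(back, X)
  # direct (x - mu) / sigma oracle
  mu <- colMeans(X); sg <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(std$x, sweep(sweep(X, 2, mu), 2, sg, "/"))
})

test_that("constant feature columns are rejected by name", {
  X <- cbind(gc1 = c(1, 1, 1), gc3 = c(0.2, 0.3, 0.4))
  expect_error(standardize_features(X), "gc1")
})

test_that("EM recovers parameters of well-separated tied Gaussians", {
  set.seed(52)
  sim <- sim_two_gaussians(1000, c(-2, -2, -2), c(2, 2, 2))
  fit <- fit_gmm_tied(sim$X, seed = 99)
  expect_true(fit$converged)
  # match components to truth by nearest mean
  o <- order(fit$means[, 1])
  expect_lt(max(abs(fit$means[o[1], ] - c(-2, -2, -2))), 0.15)
  expect_lt(max(abs(fit$means[o[2], ] - c(2, 2, 2))), 0.15)
  expect_lt(max(abs(fit$weights - 0.5)), 0.03)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(eigen(fit$covariance, only.values = TRUE)$values > 0))
})

test_that("on a single Gaussian the fit conserves the sample moments", {
  # at an EM stationary point the mixture mean equals the sample mean and
  # tied covariance + between-component scatter equals the sample
  # (population) covariance
  set.seed(53)
  X <- matrix(rnorm(3000), 1000, 3) %*% chol(toeplitz(c(1, 0.4, 0.1)))
  fit <- fit_gmm_tied(X, seed = 5)
  mu <- colMeans(X)
  mix_mean <- colSums(fit$weights * fit$means)
  expect_equal(mix_mean, mu, tolerance = 1e-3, ignore_attr = TRUE)
  S <- crossprod(sweep(X, 2, mu)) / nrow(X)
  B <- Reduce(`+`, lapply(1:2, function(k)
    fit$weights[k] * tcrossprod(fit$means[k, ] - mix_mean)))
  rel <- norm(fit$covariance + B - S, "F") / norm(S, "F")
  expect_lt(rel, 0.02)
})

test_that("the EM log-likelihood trace is non-decreasing on fuzzed runs", {
  set.seed(54)
  for (i in 1:8) {
    n <- sample(50:300, 1)
    X <- matrix(rnorm(3 * n, sd = runif(1, 0.5, 2)), n, 3) +
      rep(sample(c(-1, 1), 3, TRUE) * runif(3, 0, 2), each = n)
    fit <- fit_gmm_tied(X, seed = i, n_init = 3)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8), info = paste("run", i))
    if (fit$converged)
      expect_lt(diff(utils::tail(fit$loglik_trace, 2)), fit$tol)
  }
})

test_that("posteriors are Bayes-consistent and row-normalized", {
  model <- structure(list(
    k = 2L, weights = c(0.5, 0.5),
    means = rbind(c(-2, -2, -2), c(2, 2, 2)),
    covariance = diag(3), d = 3L), class = "nm_gmm")
  # equidistant point under equal weights
  expect_equal(as.numeric(gmm_posterior(model, rbind(c(0, 0, 0)))),
               c(0.5, 0.5))
  # a point at a component mean with large separation
  expect_gt(gmm_posterior(model, rbind(c(-2, -2, -2)))[1, 1], 0.999)

  set.seed(55)
  for (i in 1:20) {
    w <- runif(1, 0.2, 0.8)
    A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(0.5, 3)
    m <- structure(list(k = 2L, weights = c(w, 1 - w),
                        means = rbind(rnorm(3), rnorm(3)),
                        covariance = S, d = 3L), class = "nm_gmm")
    X <- matrix(rnorm(30), 10, 3)
    post <- gmm_posterior(m, X)
    expect_equal(rowSums(post), rep(1, 10), tolerance = 1e-12)
    # density-ratio oracle with an independent MVN density
    for (r in sample(10, 3)) {
      d1 <- w * oracle_mvn_density(X[r, ], m$means[1, ], S)
      d2 <- (1 - w) * oracle_mvn_density(X[r, ], m$means[2, ], S)
      expect_equal(post[r, 1], d1 / (d1 + d2), tolerance = 1e-10)
    }
  }
})

test_that("the low-G+C component is found regardless of label order", {
  std <- list(center = c(0.5, 0.4, 6), scale = c(0.1, 0.15, 1))
  m1 <- structure(list(k = 2L,
                       means = rbind(c(0, (0.30 - 0.4) / 0.15, 1),
                                     c(0, (0.55 - 0.4) / 0.15, -1)),
                       d = 3L), class = "nm_gmm")
  expect_identical(identify_low_gc_component(m1, std), 1L)
  m2 <- m1; m2$means <- m1$means[2:1, ]
  expect_identical(identify_low_gc_component(m2, std), 2L)
  # GC3 tie falls back to GC1
  m3 <- m1; m3$means <- rbind(c(-1, 0, 0), c(1, 0, 0))
  expect_identical(identify_low_gc_component(m3, std), 1L)
  m4 <- m1; m4$means <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_error(identify_low_gc_component(m4, std), "ambiguous")
})

test_that("candidate calling is strict at the threshold", {
  post <- rbind(c(0.96, 0.04), c(0.95, 0.05), c(0.50, 0.50))
  calls <- call_nm_candidates(post, 1)
  expect_identical(calls$is_nm_candidate, c(TRUE, FALSE, FALSE))
  expect_error(call_nm_candidates(post, 1, threshold = 0.4), "0.5")
})

test_that("EM agrees with an independent reference fit (mclust EEE)", {
  suppressMessages(library(mclust))
  set.seed(56)
  sim <- sim_two_gaussians(300, c(-1.5, -1.5, -1.5), c(1.5, 1.5, 1.5))
  fit <- fit_gmm_tied(sim$X, seed = 77)
  ref <- Mclust(sim$X, G = 2, modelNames = "EEE", verbose = FALSE)
  expect_equal(fit$log_likelihood / nrow(sim$X),
               ref$loglik / nrow(sim$X), tolerance = 1e-4)
})

test_that("simulate() draws reproduce the fitted mixture", {
  model <- structure(list(
    k = 2L, weights = c(0.3, 0.7),
    means = rbind(c(-3, 0, 0), c(3, 0, 0)),
    covariance = diag(3), d = 3L), class = "nm_gmm")
  X <- simulate(model, nsim = 5000, seed = 4)
  expect_equal(mean(attr(X, "component") == 1), 0.3, tolerance = 0.03)
  expect_equal(mean(X[attr(X, "component") == 1, 1]), -3, tolerance = 0.1)
})
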