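#' Standardize a feature matrix
#'
#' Centers each column to mean 0 and scales to standard deviation 1 using
#' the population (divide-by-n) standard deviation, so the transform is a
#' pure function of the data with no small-sample correction.
#'
#' @param X Numeric matrix (n x d), n >= 2, all values finite.
#' @return List with `x` (standardized matrix), `center` and `scale`
#'   (per-column parameters, usable for the inverse transform).
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) stop("X must be finite numeric")
  if (nrow(X) < 2L) stop("need at least two rows to standardize")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  scale <- sqrt(colMeans(Xc^2))
  if (any(scale <= 0)) {
    bad <- colnames(X)[scale <= 0]
    if (is.null(bad) || !length(bad)) bad <- which(scale <= 0)
    stop("degenerate input: constant feature column(s): ",
         paste(bad, collapse = ", "))
  }
  list(x = sweep(Xc, 2L, scale, "/"), center = center, scale = scale)
}

# log N(x | mu, Sigma) for all rows of X, via Cholesky
.mvn_logdensity <- function(X, mu, chol_up) {
  d <- ncol(X)
  logdet <- 2 * sum(log(diag(chol_up)))
  Z <- forwardsolve(t(chol_up), t(sweep(X, 2L, mu)))
  -0.5 * (d * log(2 * pi) + logdet + colSums(Z^2))
}

# per-row log(sum(exp(L))) without overflow
.row_logsumexp <- function(L) {
  m <- do.call(pmax, as.data.frame(L))
  m + log(rowSums(exp(L - m)))
}

# E-step: weighted log densities, returns list(logresp, ll_mean)
.estep <- function(X, weights, means, sigma) {
  U <- chol(sigma)
  L <- vapply(seq_along(weights), function(k)
    log(weights[k]) + .mvn_logdensity(X, means[k, ], U),
    numeric(nrow(X)))
  L <- matrix(L, nrow = nrow(X)) # keep matrix shape when n == 1
  lse <- .row_logsumexp(L)
  list(resp = exp(L - lse), ll_mean = mean(lse))
}

# M-step with tied covariance
.mstep <- function(X, resp, reg) {
  n <- nrow(X); d <- ncol(X); k <- ncol(resp)
  nk <- colSums(resp)
  weights <- nk / n
  means <- crossprod(resp, X) / nk
  sigma <- matrix(0, d, d)
  for (j in seq_len(k)) {
    Xc <- sweep(X, 2L, means[j, ])
    sigma <- sigma + crossprod(Xc * resp[, j], Xc)
  }
  sigma <- sigma / n + diag(reg, d)
  list(weights = weights, means = means, sigma = sigma)
}

#' Fit a Gaussian mixture with tied covariance by EM
#'
#' Expectation-maximisation for a k-component multivariate Gaussian mixture
#' in which all components share one covariance matrix. Responsibilities
#' are computed in log space with log-sum-exp; the tied covariance is the
#' responsibility-weighted pooled outer product of residuals divided by n,
#' plus `reg` on the diagonal to guarantee positive-definiteness.
#' Convergence is declared when the mean per-point log-likelihood improves
#' by less than `tol` between iterations. Each of the `n_init` seeded
#' random initializations places the component means on k distinct
#' randomly chosen data points, with equal weights and the pooled data
#' covariance; the best start by final log-likelihood is returned.
#' (Random responsibility draws, the other classic scheme, start
#' exponentially close to the symmetric fixed point where both means
#' coincide, which a tolerance-based stop misreads as convergence.)
#'
#' @param X Numeric matrix of observations (rows), already standardized if
#'   desired; `n > k` required.
#' @param k Number of components (default 2).
#' @param seed Integer seed for the initialization draws (required: runs
#'   must be reproducible).
#' @param n_init Number of random restarts (default 10).
#' @param tol Convergence tolerance on mean per-point log-likelihood
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param reg Diagonal covariance regularization (default 1e-6).
#' @return An object of class `nm_gmm`: list with `weights`, `means`
#'   (k x d), `covariance` (d x d, tied), `log_likelihood` (total, at the
#'   optimum), `loglik_trace` (mean per-point log-likelihood per iteration
#'   of the winning start), `n_iter`, `converged`, plus the call
#'   parameters.
#' @export
fit_gmm_tied <- function(X, k = 2L, seed, n_init = 10L, tol = 1e-6,
                         max_iter = 500L, reg = 1e-6) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("X must be a finite numeric matrix")
  n <- nrow(X); d <- ncol(X)
  if (n <= k) stop("need more observations than components")
  if (missing(seed)) stop("'seed' is required for reproducible fits")
  set.seed(seed)
  Xc <- sweep(X, 2L, colMeans(X))
  pooled_cov <- crossprod(Xc) / n + diag(reg, d)
  best <- NULL
  for (init in seq_len(n_init)) {
    par <- list(weights = rep(1 / k, k),
                means = X[sample.int(n, k), , drop = FALSE],
                sigma = pooled_cov)
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      es <- tryCatch(.estep(X, par$weights, par$means, par$sigma),
                     error = function(e)
                       stop("numerical failure: covariance not ",
                            "positive-definite despite regularization"))
      trace <- c(trace, es$ll_mean)
      if (es$ll_mean - ll_prev < tol && iter > 1L) {
        converged <- TRUE
        break
      }
      ll_prev <- es$ll_mean
      par <- .mstep(X, es$resp, reg)
    }
    ll_final <- trace[length(trace)]
    if (is.null(best) || ll_final > best$ll) {
      best <- list(par = par, ll = ll_final, trace = trace,
                   n_iter = iter, converged = converged)
    }
  }
  structure(list(
    k = as.integer(k),
    weights = as.numeric(best$par$weights),
    means = unname(best$par$means),
    covariance = unname(best$par$sigma),
    log_likelihood = best$ll * n,
    loglik_trace = best$trace,
    n_iter = best$n_iter,
    converged = best$converged,
    n = n, d = d,
    seed = seed, n_init = n_init, tol = tol,
    max_iter = max_iter, reg = reg
  ), class = "nm_gmm")
}

#' Posterior component responsibilities
#'
#' Bayes' rule on the component Gaussian log-densities, computed with
#' log-sum-exp; every row sums to 1.
#'
#' @param model An `nm_gmm` fit.
#' @param X Matrix of points on the same (standardized) scale the model
#'   was fitted on.
#' @return n x k matrix of posterior probabilities.
#' @export
gmm_posterior <- function(model, X) {
  stopifnot(inherits(model, "nm_gmm"))
  X <- as.matrix(X)
  .estep(X, model$weights, model$means, model$covariance)$resp
}

#' @export
print.nm_gmm <- function(x, ...) {
  cat("Gaussian mixture (tied covariance), k =", x$k,
      "on", x$n, "points,", x$d, "features\n")
  cat("  weights:", format(x$weights, digits = 4), "\n")
  cat("  log-likelihood:", format(x$log_likelihood, digits = 8),
      if (x$converged) "(converged" else "(NOT converged",
      "in", x$n_iter, "iterations)\n")
  invisible(x)
}

#' @export
#' @method coef nm_gmm
coef.nm_gmm <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       covariance = object$covariance)
}

#' @export
#' @method logLik nm_gmm
logLik.nm_gmm <- function(object, ...) {
  df <- (object$k - 1) + object$k * object$d +
    object$d * (object$d + 1) / 2
  structure(object$log_likelihood, df = df, nobs = object$n,
            class = "logLik")
}

#' @export
predict.nm_gmm <- function(object, newdata, type = c("posterior", "class"),
                           ...) {
  type <- match.arg(type)
  post <- gmm_posterior(object, newdata)
  if (type == "posterior") post else max.col(post)
}

#' Draw observations from a fitted mixture
#'
#' @param object An `nm_gmm` fit.
#' @param nsim Number of points.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return `nsim` x d matrix with a `component` attribute.
#' @export
simulate.nm_gmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
  U <- chol(object$covariance)
  Z <- matrix(stats::rnorm(nsim * object$d), nsim, object$d) %*% U
  out <- object$means[comp, , drop = FALSE] + Z
  attr(out, "component") <- comp
  out
}

#' Identify the low-G+C mixture component
#'
#' Components are compared on their de-standardized mean GC3 (the least
#' constrained codon position and the most diagnostic of genome-wide
#' compositional pressure); ties are broken by mean GC1. Feature order
#' must be (gc1, gc3, ln_tpm).
#'
#' @param model An `nm_gmm` fit on standardized features.
#' @param standardization The list returned by [standardize_features()].
#' @return Component index (1-based) of the low-G+C component.
#' @export
identify_low_gc_component <- function(model, standardization) {
  m <- sweep(sweep(model$means, 2L, standardization$scale, "*"),
             2L, standardization$center, "+")
  gc3 <- m[, 2L]; gc1 <- m[, 1L]
  if (gc3[1L] != gc3[2L]) return(which.min(gc3))
  if (gc1[1L] != gc1[2L]) return(which.min(gc1))
  stop("ambiguous model: components have identical mean GC3 and GC1")
}

#' Call nucleomorph candidates from posterior probabilities
#'
#' A transcript is a candidate iff its posterior probability of belonging
#' to the low-G+C component is strictly greater than the threshold
#' (posterior exactly at the threshold is not a candidate).
#'
#' @param posteriors n x k posterior matrix from [gmm_posterior()].
#' @param low_idx Index of the low-G+C component.
#' @param threshold Posterior threshold in (0.5, 1); default 0.95.
#' @return Data.frame `posterior_low_gc`, `is_nm_candidate`.
#' @export
call_nm_candidates <- function(posteriors, low_idx, threshold = 0.95) {
  if (!(threshold > 0.5 && threshold < 1))
    stop("'threshold' must be in (0.5, 1)")
  p <- posteriors[, low_idx]
  data.frame(posterior_low_gc = p, is_nm_candidate = p > threshold)
}
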