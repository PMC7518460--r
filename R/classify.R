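#' Classify transcripts into nuclear and nucleomorph populations
#'
#' The central fitting function. Takes one row per transcript with the
#' three features the classifier uses — G+C fraction at codon positions 1
#' and 3 of the longest ORF, and natural log of TPM — standardizes them,
#' fits a two-component Gaussian mixture with tied covariance by EM, finds
#' the component with the lower (de-standardized) mean GC3, and calls a
#' transcript a nucleomorph candidate when its posterior probability of
#' that component strictly exceeds `threshold`.
#'
#' @param features Data.frame with columns `transcript_id`, `gc1`, `gc3`,
#'   `ln_tpm` (all finite; exclude zero-TPM transcripts beforehand, see
#'   [ln_tpm()]).
#' @param threshold Posterior call threshold, default 0.95.
#' @param seed Integer seed for EM initialization.
#' @param n_init,tol,max_iter,reg Passed to [fit_gmm_tied()].
#' @return An object of class `nm_fit` with components `model` (the
#'   [fit_gmm_tied()] object), `standardization`, `low_component`,
#'   `threshold` and `calls` (data.frame `transcript_id, gc1, gc3, ln_tpm,
#'   posterior_low_gc, is_nm_candidate`). Supports `print()`, `summary()`,
#'   `coef()`, `predict()` and `plot()`.
#' @examples
#' set.seed(1)
#' n <- 200
#' feats <- data.frame(
#'   transcript_id = sprintf("t%03d", 1:(2 * n)),
#'   gc1 = c(rnorm(n, 0.40, 0.04), rnorm(n, 0.55, 0.04)),
#'   gc3 = c(rnorm(n, 0.25, 0.05), rnorm(n, 0.55, 0.05)),
#'   ln_tpm = c(rnorm(n, 7.5, 1), rnorm(n, 5.5, 1)))
#' fit <- nm_classify(feats, seed = 1, n_init = 2)
#' fit
#' @export
nm_classify <- function(features, threshold = 0.95, seed = 1L,
                        n_init = 10L, tol = 1e-6, max_iter = 500L,
                        reg = 1e-6) {
  need <- c("transcript_id", "gc1", "gc3", "ln_tpm")
  if (!is.data.frame(features) || !all(need %in% names(features)))
    stop("'features' needs columns: ", paste(need, collapse = ", "))
  X <- as.matrix(features[, c("gc1", "gc3", "ln_tpm")])
  if (any(!is.finite(X)))
    stop("non-finite feature values; remove zero-TPM transcripts first")
  std <- standardize_features(X)
  model <- fit_gmm_tied(std$x, k = 2L, seed = seed, n_init = n_init,
                        tol = tol, max_iter = max_iter, reg = reg)
  low <- identify_low_gc_component(model, std)
  post <- gmm_posterior(model, std$x)
  calls <- cbind(
    features[, need, drop = FALSE],
    call_nm_candidates(post, low, threshold)
  )
  rownames(calls) <- NULL
  structure(list(model = model, standardization = std[c("center", "scale")],
                 low_component = low, threshold = threshold, calls = calls),
            class = "nm_fit")
}

#' @export
print.nm_fit <- function(x, ...) {
  n <- nrow(x$calls)
  nc <- sum(x$calls$is_nm_candidate)
  cat("Nucleomorph-candidate classification (2-component tied-covariance",
      "Gaussian mixture)\n")
  cat(sprintf("  %d transcripts clustered; %d Nm-candidates at posterior > %g\n",
              n, nc, x$threshold))
  cat(sprintf("  low-G+C component: %d (weight %.3f)\n",
              x$low_component, x$model$weights[x$low_component]))
  invisible(x)
}

#' @export
#' @method summary nm_fit
summary.nm_fit <- function(object, ...) {
  m <- sweep(sweep(object$model$means, 2L, object$standardization$scale,
                   "*"), 2L, object$standardization$center, "+")
  colnames(m) <- c("gc1", "gc3", "ln_tpm")
  rownames(m) <- ifelse(seq_len(2L) == object$low_component,
                        "low_gc (nucleomorph)", "high_gc (nuclear)")
  out <- list(
    n = nrow(object$calls),
    n_candidates = sum(object$calls$is_nm_candidate),
    threshold = object$threshold,
    weights = object$model$weights,
    component_means = m,
    log_likelihood = object$model$log_likelihood,
    converged = object$model$converged
  )
  class(out) <- "summary.nm_fit"
  out
}

#' @export
print.summary.nm_fit <- function(x, ...) {
  cat(sprintf("%d transcripts, %d Nm-candidates (posterior > %g)\n",
              x$n, x$n_candidates, x$threshold))
  cat("component means (original feature scale):\n")
  print(round(x$component_means, 4))
  cat("weights:", format(x$weights, digits = 4), "\n")
  cat("log-likelihood:", format(x$log_likelihood, digits = 8),
      if (x$converged) "(converged)\n" else "(not converged)\n")
  invisible(x)
}

#' @export
#' @method coef nm_fit
coef.nm_fit <- function(object, ...) coef(object$model)

#' Posterior calls for new transcripts under a fitted classification
#'
#' @param object An `nm_fit`.
#' @param newdata Data.frame with columns `transcript_id`, `gc1`, `gc3`,
#'   `ln_tpm`; defaults to the training features.
#' @param ... Unused.
#' @return Data.frame of calls as in `object$calls`.
#' @export
predict.nm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$calls)
  X <- as.matrix(newdata[, c("gc1", "gc3", "ln_tpm")])
  Xs <- sweep(sweep(X, 2L, object$standardization$center), 2L,
              object$standardization$scale, "/")
  post <- gmm_posterior(object$model, Xs)
  cbind(newdata[, "transcript_id", drop = FALSE],
        newdata[, c("gc1", "gc3", "ln_tpm")],
        call_nm_candidates(post, object$low_component, object$threshold))
}

#' Scatter/histogram view of a classification
#'
#' GC1 vs GC3 scatter coloured by call, with a marginal GC3 histogram on
#' top — the figure the candidate table is usually inspected with.
#'
#' @param x An `nm_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
#' @method plot nm_fit
plot.nm_fit <- function(x, ...) {
  calls <- x$calls
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  graphics::layout(matrix(1:2, 2L), heights = c(1, 2.4))
  graphics::par(mar = c(0.5, 4, 1, 1))
  brk <- seq(0, 1, by = 0.02)
  h1 <- graphics::hist(calls$gc3[calls$is_nm_candidate], breaks = brk,
                       plot = FALSE)
  h2 <- graphics::hist(calls$gc3[!calls$is_nm_candidate], breaks = brk,
                       plot = FALSE)
  ylim <- c(0, max(h1$counts, h2$counts))
  graphics::plot(h1, col = grDevices::adjustcolor("darkgreen", 0.6),
                 border = NA, xlim = c(0, 1), ylim = ylim, main = "",
                 xaxt = "n", xlab = "", ylab = "count")
  graphics::plot(h2, col = grDevices::adjustcolor("palegreen3", 0.6),
                 border = NA, add = TRUE)
  graphics::par(mar = c(4, 4, 0.5, 1))
  graphics::plot(calls$gc3, calls$gc1,
                 col = ifelse(calls$is_nm_candidate, "darkgreen",
                              "palegreen3"),
                 pch = 16, cex = 0.6, xlim = c(0, 1),
                 xlab = "G+C at codon position 3",
                 ylab = "G+C at codon position 1", ...)
  graphics::legend("topleft", pch = 16,
                   col = c("darkgreen", "palegreen3"),
                   legend = c("Nm-candidate", "nuclear"), bty = "n")
  invisible(x)
}
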