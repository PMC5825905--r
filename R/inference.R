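#' Bootstrap standard errors and percentile confidence intervals
#'
#' Nonparametric bootstrap for the path coefficients of a consistent PLS fit:
#' rows are resampled with replacement, the full estimation pipeline (weights,
#' reliabilities, disattenuation, least squares) is re-run on every resample,
#' and each coefficient's standard error and percentile confidence interval
#' are read off the bootstrap distribution. A path is declared significant
#' when its interval excludes zero.
#'
#' Within each resample the disattenuated correlations are projected onto the
#' admissible range \eqn{[-1, 1]}: disattenuation is a ratio estimator whose
#' raw resample values can leave the correlation parameter space under weak
#' reliability, and the projection keeps resample coefficient draws from
#' exploding. For `method = "regplsc"` the regularization parameter is
#' selected once on the full sample and held fixed across resamples, so the
#' intervals reflect sampling variability at the chosen amount of shrinkage;
#' `reselect_lambda = TRUE` re-runs cross-validation inside every resample for
#' sensitivity analysis (roughly K + 1 times slower per resample). Resamples
#' on which estimation fails (weight non-convergence, a zero-variance column,
#' a singular structural equation) are counted and excluded; more than 50%
#' failures aborts with an unstable-inference error.
#'
#' @param data indicator data matrix.
#' @param model a [plsc_model()].
#' @param method `"plsc"` or `"regplsc"`.
#' @param B number of bootstrap resamples (default 5000; simulation studies
#'   commonly use 200).
#' @param alpha two-sided significance level of the percentile interval.
#' @param seed RNG seed (restored on exit); identical seeds give bit-identical
#'   summaries.
#' @param reselect_lambda re-run [select_lambda()] inside each resample.
#' @param lambda,K,grid,scheme,tol,max_iter passed to [plsc_fit()].
#' @return object of class `plsc_boot`: `summary` data.frame (`path`,
#'   `estimate`, `se`, `lower`, `upper`, `reject`), the full-sample `fit`,
#'   `B`, `failed`, `alpha`.
#' @export
plsc_bootstrap <- function(data, model, method = c("plsc", "regplsc"),
                           B = 5000L, alpha = 0.05, seed = NULL,
                           reselect_lambda = FALSE, lambda = NULL, K = NULL,
                           grid = default_lambda_grid(), scheme = "path",
                           tol = 1e-6, max_iter = 300L) {
  method <- match.arg(method)
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  X <- as.matrix(data)
  N <- nrow(X)
  local_seed(seed)
  # cross-validation inside the fit restores the RNG state (its own seed), so
  # the resampling stream below is unaffected by the method's tuning step and
  # plsc/regplsc runs with equal seeds see identical resamples
  fit <- plsc_fit(X, model, method = method, lambda = lambda, K = K,
                  grid = grid, seed = if (is.null(seed)) 1L else seed,
                  scheme = scheme, tol = tol, max_iter = max_iter)
  eqs <- structural_equations(model)
  layout <- pls_layout(model, colnames(X))
  lam <- fit$lambda
  w_full <- unname(fit$weights$weights)
  draws <- matrix(NA_real_, B, length(fit$coefficients),
                  dimnames = list(NULL, names(fit$coefficients)))
  for (b in seq_len(B)) {
    res <- tryCatch({
      Xb <- X[sample.int(N, N, replace = TRUE), , drop = FALSE]
      if (reselect_lambda && method == "regplsc")
        lam <- select_lambda(Xb, model, K = K, grid = grid, scheme = scheme,
                             tol = tol, max_iter = max_iter)$lambda
      boot_refit(Xb, layout, eqs, method, lam, scheme, tol, max_iter, w_full)
    }, error = function(e) NULL)
    if (!is.null(res) && all(is.finite(res))) draws[b, ] <- res
  }
  failed <- sum(!stats::complete.cases(draws))
  if (failed > B / 2)
    stop(errorCondition(
      sprintf("unstable inference: %d of %d bootstrap resamples failed", failed, B),
      class = c("plsc_unstable_inference", "error", "condition")))
  kept <- draws[stats::complete.cases(draws), , drop = FALSE]
  smry <- boot_summarize(kept, fit$coefficients, alpha)
  structure(list(summary = smry, fit = fit, B = B, failed = failed,
                 alpha = alpha, method = method),
            class = "plsc_boot")
}

# One bootstrap refit at fixed lambda; raw coefficient vector or error.
# Warm-started from the full-sample weights (the fixed point is unique, the
# start only shortens the iteration).
boot_refit <- function(Xb, layout, eqs, method, lam, scheme, tol, max_iter,
                       w_init = NULL) {
  core <- consistent_core(Xb, layout, scheme, tol, max_iter, w_init = w_init,
                          from_data = TRUE, clamp_r = TRUE)
  solve_paths_core(core$R, eqs, if (method == "plsc") rep(0, length(eqs)) else lam)
}

# Percentile summary: linear interpolation between order statistics
# (stats::quantile type 7).
boot_summarize <- function(kept, estimate, alpha) {
  lo <- apply(kept, 2, stats::quantile, probs = alpha / 2, type = 7, names = FALSE)
  hi <- apply(kept, 2, stats::quantile, probs = 1 - alpha / 2, type = 7, names = FALSE)
  data.frame(
    path = colnames(kept),
    estimate = as.numeric(estimate[colnames(kept)]),
    se = apply(kept, 2, stats::sd),
    lower = lo, upper = hi,
    reject = lo > 0 | hi < 0,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.plsc_boot <- function(x, ...) {
  cat(sprintf("Bootstrap inference (%s, B = %d, %d failed, %.0f%% percentile CI)\n",
              x$method, x$B, x$failed, 100 * (1 - x$alpha)))
  out <- x$summary
  out[, c("estimate", "se", "lower", "upper")] <-
    round(out[, c("estimate", "se", "lower", "upper")], 4)
  print(out)
  invisible(x)
}
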