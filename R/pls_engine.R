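#' Standardize an indicator data matrix
#'
#' Columnwise centering and scaling to unit variance with divisor N - 1.
#'
#' @param X numeric matrix, rows = observations.
#' @return standardized matrix with attributes `center` and `scale`.
#' @export
standardize_data <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("indicator data contain missing values", call. = FALSE)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- X - rep(ctr, each = n)
  scl <- sqrt(colSums(Xc^2) / (n - 1))
  if (any(scl <= 0)) {
    bad <- colnames(X)[scl <= 0]
    stop(errorCondition(
      paste0("zero-variance indicator column(s): ",
             paste(if (length(bad)) bad else which(scl <= 0), collapse = ", ")),
      class = c("plsc_degenerate_data", "error", "condition")))
  }
  Xs <- Xc / rep(scl, each = n)
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  Xs
}

# Internal bookkeeping shared by the weight engine: indicator indices per
# block, parent/child latent indices, and linear indices of the nonzero
# weight slots, all relative to a fixed column order.
pls_layout <- function(model, columns) {
  miss <- setdiff(model$indicators, columns)
  if (length(miss))
    stop("data lack indicator column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lvs <- model$lv_names
  p <- length(columns)
  L <- length(lvs)
  blk <- lapply(model$blocks, function(b) match(b, columns))
  par <- lapply(lvs, function(lv) match(model$paths$source[model$paths$target == lv], lvs))
  chd <- lapply(lvs, function(lv) match(model$paths$target[model$paths$source == lv], lvs))
  names(par) <- names(chd) <- lvs
  list(lvs = lvs, p = p, L = L, blk = blk, par = par, chd = chd,
       blk0 = lapply(blk, function(i) i - 1L),
       par0 = lapply(par, function(i) i - 1L),
       chd0 = lapply(chd, function(i) i - 1L))
}

# Direct solution of tiny symmetric linear systems (structural equations
# rarely have more than a handful of predictors); falls back to solve().
solve_small <- function(A, b) {
  n <- length(b)
  if (n == 1L) return(b / A[1L])
  if (n == 2L) {
    dt <- A[1L] * A[4L] - A[2L] * A[3L]
    return(c(A[4L] * b[1L] - A[3L] * b[2L],
             A[1L] * b[2L] - A[2L] * b[1L]) / dt)
  }
  if (n == 3L) {
    # Cramer's rule; A is column-major: a11=A[1], a21=A[2], ..., a33=A[9]
    i11 <- A[5L] * A[9L] - A[8L] * A[6L]
    i12 <- A[7L] * A[6L] - A[4L] * A[9L]
    i13 <- A[4L] * A[8L] - A[7L] * A[5L]
    dt <- A[1L] * i11 + A[2L] * i12 + A[3L] * i13
    return(c(
      b[1L] * i11 + b[2L] * i12 + b[3L] * i13,
      b[1L] * (A[8L] * A[3L] - A[2L] * A[9L]) +
        b[2L] * (A[1L] * A[9L] - A[7L] * A[3L]) +
        b[3L] * (A[7L] * A[2L] - A[1L] * A[8L]),
      b[1L] * (A[2L] * A[6L] - A[5L] * A[3L]) +
        b[2L] * (A[4L] * A[3L] - A[1L] * A[6L]) +
        b[3L] * (A[1L] * A[5L] - A[4L] * A[2L])
    ) / dt)
  }
  solve(A, b)
}

scheme_code <- function(scheme) {
  match(scheme, c("path", "centroid", "factorial")) - 1L
}

# Raise the R-level condition corresponding to a compiled-core status code.
core_status_stop <- function(res, max_iter) {
  if (res$status == 1L)
    stop(errorCondition(
      sprintf("Mode A weights did not converge in %d iterations", max_iter),
      class = c("plsc_convergence_error", "error", "condition"),
      weights = res$W, iterations = res$iterations))
  if (res$status == 3L)
    stop(errorCondition("zero-variance indicator column",
                        class = c("plsc_degenerate_data", "error", "condition")))
  stop(errorCondition("degenerate composite (nonpositive variance or reliability)",
                      class = c("plsc_degenerate_data", "error", "condition")))
}

# Mode A fixed-point iteration expressed entirely in terms of the indicator
# correlation matrix S (compiled core). Weights are normalized to unit
# composite variance (w' S_block w = 1) with a positive weight-sum sign
# convention each sweep.
pls_weights_core <- function(S, layout, scheme = "path", tol = 1e-6,
                             max_iter = 300L, w_init = NULL) {
  res <- cpp_pls_weights(S, layout$blk0, layout$par0, layout$chd0,
                         scheme_code(scheme), tol, as.integer(max_iter),
                         if (is.null(w_init)) NULL else
                           as.numeric(unlist(w_init, use.names = FALSE)))
  if (res$status != 0L) core_status_stop(res, max_iter)
  list(W = res$W, iterations = res$iterations, converged = TRUE)
}

#' Estimate Mode A indicator weights
#'
#' Runs the iterative PLS algorithm for reflective (Mode A) blocks: composite
#' scores are formed from the current weights, combined into inner proxies
#' under the chosen inner weighting scheme, and the weights of each block are
#' updated as the covariances between its indicators and the block's inner
#' proxy, normalized to unit composite variance. Iteration stops when the
#' largest absolute weight change falls below `tol`.
#'
#' @param data numeric matrix or data.frame of indicator scores (rows =
#'   observations); standardized internally unless `standardized = TRUE`.
#' @param model a [plsc_model()].
#' @param scheme inner weighting scheme: `"path"` (default), `"centroid"` or
#'   `"factorial"`.
#' @param tol convergence tolerance on the maximum absolute weight change.
#' @param max_iter iteration cap; exceeding it raises a convergence error
#'   (condition class `plsc_convergence_error`) carrying the last iterate.
#' @param standardized set `TRUE` if `data` are already standardized
#'   (mean 0, variance 1 with divisor N - 1).
#' @param w_init optional list of starting weight vectors, one per block
#'   (defaults to equal weights).
#' @return object of class `plsc_weights`: per-block weight vectors, the full
#'   sparse weight matrix `W`, iteration count and convergence flag.
#' @examples
#' pop <- build_population(list(N = 60, phi = 0.4, reliability = 0.8, r2 = 0.25))
#' X <- generate_sample(pop, 100, seed = 1)
#' w <- estimate_weights(X, pop$model)
#' @export
estimate_weights <- function(data, model, scheme = c("path", "centroid", "factorial"),
                             tol = 1e-6, max_iter = 300L, standardized = FALSE,
                             w_init = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(data)
  if (is.null(colnames(X)))
    stop("data must carry indicator column names", call. = FALSE)
  if (!standardized) X <- standardize_data(X)
  layout <- pls_layout(model, colnames(X))
  S <- crossprod(X) / (nrow(X) - 1)
  new_plsc_weights(
    pls_weights_core(S, layout, scheme, tol, max_iter, w_init),
    model, colnames(X), scheme)
}

#' @describeIn estimate_weights Estimate weights from exact second-order
#'   moments: `S` is an indicator correlation (or covariance) matrix, e.g. a
#'   population `Sigma`, in lieu of raw data. Supports analytic,
#'   population-level computation.
#' @param S indicator correlation matrix with dimnames covering the model's
#'   indicators.
#' @export
estimate_weights_moments <- function(S, model, scheme = c("path", "centroid", "factorial"),
                                     tol = 1e-6, max_iter = 300L, w_init = NULL) {
  scheme <- match.arg(scheme)
  S <- as.matrix(S)
  if (is.null(colnames(S)))
    stop("moment matrix must carry indicator names", call. = FALSE)
  layout <- pls_layout(model, colnames(S))
  new_plsc_weights(
    pls_weights_core(S, layout, scheme, tol, max_iter, w_init),
    model, colnames(S), scheme)
}

new_plsc_weights <- function(core, model, columns, scheme) {
  W <- core$W
  dimnames(W) <- list(columns, model$lv_names)
  weights <- lapply(model$lv_names, function(lv)
    stats::setNames(W[model$blocks[[lv]], lv], model$blocks[[lv]]))
  names(weights) <- model$lv_names
  structure(list(W = W, weights = weights, iterations = core$iterations,
                 converged = core$converged, model = model, scheme = scheme),
            class = "plsc_weights")
}

#' @export
print.plsc_weights <- function(x, ...) {
  cat(sprintf("Mode A weights (%s scheme), converged in %d iterations\n",
              x$scheme, x$iterations))
  for (lv in names(x$weights))
    cat(" ", lv, ":", paste(sprintf("%.4f", x$weights[[lv]]), collapse = " "), "\n")
  invisible(x)
}

#' Composite (latent variable proxy) scores
#'
#' Applies estimated Mode A weights to standardized indicator data, yielding
#' one score column per latent variable. When the weights were estimated on
#' the same data, each column has unit variance (divisor N - 1).
#'
#' @param data indicator data matrix.
#' @param weights a [estimate_weights()] result.
#' @param standardized set `TRUE` if `data` are already standardized.
#' @return N x L matrix of composite scores.
#' @export
composite_scores <- function(data, weights, standardized = FALSE) {
  stopifnot(inherits(weights, "plsc_weights"))
  X <- as.matrix(data)
  if (is.null(colnames(X)))
    stop("data must carry indicator column names", call. = FALSE)
  miss <- setdiff(rownames(weights$W), colnames(X))
  if (length(miss))
    stop("data lack indicator column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(vapply(weights$weights, function(w) all(w == 0), logical(1))))
    stop("all-zero weight vector violates the unit-variance normalization",
         call. = FALSE)
  if (!standardized) X <- standardize_data(X)
  X[, rownames(weights$W), drop = FALSE] %*% weights$W
}

#' Correlations between composite scores
#'
#' @param scores N x L composite score matrix (N >= 2).
#' @return symmetric unit-diagonal L x L correlation matrix.
#' @export
proxy_correlations <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(scores, 2, stats::sd)
  if (any(sds <= 0 | !is.finite(sds)))
    stop(errorCondition("constant composite score column",
                        class = c("plsc_degenerate_data", "error", "condition")))
  R <- stats::cor(scores)
  diag(R) <- 1
  (R + t(R)) / 2
}
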