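#' Consistent reliability coefficient rho_A
#'
#' The Dijkstra-Henseler consistent reliability of a Mode A composite,
#' \deqn{\hat\rho_A = (\hat w'\hat w)^2 \,
#'   \frac{\hat w'(S - \mathrm{diag}(S))\hat w}
#'        {\hat w'(\hat w \hat w' - \mathrm{diag}(\hat w\hat w'))\hat w},}
#' where \eqn{\hat w} is the block's estimated weight vector and \eqn{S} the
#' block's sample covariance matrix. Values outside (0, 1] are retained and
#' flagged rather than clamped; downstream positive-definiteness checks decide
#' what to do with them.
#'
#' @param w numeric weight vector (length >= 2).
#' @param S block covariance matrix, same dimension as `w`.
#' @return list with elements `value` and `valid` (`TRUE` iff value in (0, 1]).
#' @examples
#' S <- matrix(0.5, 4, 4); diag(S) <- 1
#' rho_a(rep(sqrt(0.1), 4), S)$value # 0.8
#' @export
rho_a <- function(w, S) {
  w <- as.numeric(w)
  if (length(w) < 2) stop("a block needs at least 2 indicators", call. = FALSE)
  S <- as.matrix(S)
  stopifnot(nrow(S) == length(w), ncol(S) == length(w))
  ww <- sum(w * w)
  num <- drop(crossprod(w, S %*% w)) - sum(w^2 * diag(S))
  den <- ww^2 - sum(w^4)
  if (den == 0)
    stop(errorCondition("reliability undefined: single effective indicator",
                        class = c("plsc_undefined_reliability", "error", "condition")))
  val <- ww^2 * num / den
  list(value = val, valid = is.finite(val) && val > 0 && val <= 1)
}

#' Consistent reliabilities for all blocks
#'
#' Evaluates [rho_a()] for every latent variable's block using its estimated
#' weights and the corresponding submatrix of the indicator covariance matrix.
#'
#' @param weights a [estimate_weights()] result.
#' @param S full indicator covariance/correlation matrix with dimnames.
#' @return data.frame with columns `lv`, `rho_a`, `valid`.
#' @export
reliabilities <- function(weights, S) {
  stopifnot(inherits(weights, "plsc_weights"))
  model <- weights$model
  out <- lapply(model$lv_names, function(lv) {
    ind <- model$blocks[[lv]]
    rho_a(weights$weights[[lv]], S[ind, ind, drop = FALSE])
  })
  data.frame(lv = model$lv_names,
             rho_a = vapply(out, `[[`, numeric(1), "value"),
             valid = vapply(out, `[[`, logical(1), "valid"),
             stringsAsFactors = FALSE)
}

#' Correct proxy correlations for attenuation
#'
#' Divides every off-diagonal proxy correlation by the square root of the
#' product of the two composites' reliabilities, recovering consistent
#' latent-variable correlations. Entries may leave [-1, 1] in small samples;
#' they are retained (not truncated) and the positive-definiteness flag
#' records whether the matrix is usable for least squares.
#'
#' @param R_proxy L x L composite correlation matrix.
#' @param rho numeric vector of reliabilities (all > 0), or the data.frame
#'   returned by [reliabilities()].
#' @return object of class `plsc_consistent_cor`: list with `R` (disattenuated
#'   matrix), `pd` (smallest eigenvalue > 1e-10) and `min_eigenvalue`.
#' @examples
#' R <- matrix(c(1, .32, .32, 1), 2)
#' disattenuate(R, c(0.8, 0.8))$R[1, 2] # 0.4
#' @export
disattenuate <- function(R_proxy, rho) {
  if (is.data.frame(rho)) rho <- rho$rho_a
  rho <- as.numeric(rho)
  R_proxy <- as.matrix(R_proxy)
  stopifnot(nrow(R_proxy) == length(rho))
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("reliabilities must be positive and finite for disattenuation",
         call. = FALSE)
  R <- R_proxy / sqrt(outer(rho, rho))
  diag(R) <- 1
  R <- (R + t(R)) / 2
  dimnames(R) <- dimnames(R_proxy)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  structure(list(R = R, pd = min(ev) > 1e-10, min_eigenvalue = min(ev)),
            class = "plsc_consistent_cor")
}

#' @export
print.plsc_consistent_cor <- function(x, ...) {
  cat(sprintf("Consistent latent correlations (%s, smallest eigenvalue %.3g)\n",
              if (x$pd) "positive definite" else "NOT positive definite",
              x$min_eigenvalue))
  print(round(x$R, 4))
  invisible(x)
}

#' Ordinary and ridge least squares on correlation input
#'
#' `ols_paths()` solves \eqn{R_X \beta = r_{Xy}}; `ridge_paths()` solves
#' \eqn{(R_X + \lambda I)\beta = r_{Xy}}. Both operate on consistent
#' (disattenuated) correlations, so the coefficients are standardized.
#' `ridge_paths(..., lambda = 0)` reproduces `ols_paths()` exactly.
#'
#' @param Rx predictor correlation matrix (possibly 1 x 1).
#' @param rxy vector of predictor-outcome correlations.
#' @param lambda ridge regularization parameter, >= 0.
#' @return numeric coefficient vector.
#' @examples
#' Rx <- matrix(c(1, .5, .5, 1), 2)
#' ols_paths(Rx, c(0.6, 0.4))
#' ridge_paths(Rx, c(0.6, 0.4), lambda = 0.1)
#' @export
ols_paths <- function(Rx, rxy) {
  Rx <- as.matrix(Rx)
  rxy <- as.numeric(rxy)
  stopifnot(nrow(Rx) == ncol(Rx), nrow(Rx) == length(rxy))
  ev <- eigen(Rx, symmetric = TRUE, only.values = TRUE)$values
  rc <- min(abs(ev)) / max(abs(ev))
  if (!is.finite(rc) || rc < 1e-12)
    stop(errorCondition(
      sprintf("singular predictor correlation matrix (reciprocal condition %.2e)", rc),
      class = c("plsc_singular_error", "error", "condition"),
      min_eigenvalue = min(ev)))
  drop(solve(Rx, rxy))
}

#' @rdname ols_paths
#' @export
ridge_paths <- function(Rx, rxy, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  Rx <- as.matrix(Rx)
  rxy <- as.numeric(rxy)
  stopifnot(nrow(Rx) == ncol(Rx), nrow(Rx) == length(rxy))
  if (lambda == 0) return(ols_paths(Rx, rxy))
  drop(solve(Rx + diag(lambda, nrow(Rx)), rxy))
}

#' Default regularization-parameter grid
#'
#' Zero (falling back to ordinary PLSc) plus 30 logarithmically spaced values
#' between 1e-4 and 1; the tuning parameter is typically a small positive
#' constant on the correlation scale.
#'
#' @return increasing numeric vector of 31 candidate values.
#' @export
default_lambda_grid <- function() {
  c(0, 10^seq(log10(1e-4), 0, length.out = 30))
}

# Structural equations in topological order, with indices into lv_names.
structural_equations <- function(model) {
  lvs <- model$lv_names
  eqs <- lapply(intersect(model$order, model$endogenous), function(lv) {
    rows <- which(model$paths$target == lv)
    list(target = lv, target_i = match(lv, lvs),
         parents = model$paths$source[rows],
         parents_i = match(model$paths$source[rows], lvs),
         labels = model$paths$label[rows])
  })
  names(eqs) <- vapply(eqs, `[[`, character(1), "target")
  eqs
}

# Steps 1-2 on a correlation matrix: weights, rho_A, disattenuation
# (compiled core). Returns raw numbers only; hot path for the simulation
# harness. `from_data` takes a raw data matrix instead and standardizes
# internally (divisor N - 1).
consistent_core <- function(S, layout, scheme = "path", tol = 1e-6,
                            max_iter = 300L, w_init = NULL, from_data = FALSE,
                            rho_fixed = NULL, clamp_r = FALSE) {
  fn <- if (from_data) cpp_consistent_from_data else cpp_consistent_core
  res <- fn(S, layout$blk0, layout$par0, layout$chd0, scheme_code(scheme),
            tol, as.integer(max_iter),
            if (is.null(w_init)) NULL else
              as.numeric(unlist(w_init, use.names = FALSE)),
            rho_fixed, clamp_r)
  if (res$status != 0L) core_status_stop(res, max_iter)
  list(W = res$W, iterations = res$iterations, rho = drop(res$rho),
       rho_valid = is.finite(res$rho) & res$rho > 0 & res$rho <= 1,
       proxy = res$proxy, R = res$R, min_eig = res$min_eig,
       pd = res$min_eig > 1e-10)
}

# Per-equation path solve from a consistent correlation matrix.
# lambda is a vector over equations. With guard = TRUE, lambda = 0 equations
# go through ols_paths() and its explicit singularity diagnostics; the
# unguarded path is used where positive definiteness is already established.
solve_paths_core <- function(Rc, eqs, lambda, guard = TRUE) {
  coefs <- unlist(lapply(seq_along(eqs), function(k) {
    eq <- eqs[[k]]
    Rx <- Rc[eq$parents_i, eq$parents_i, drop = FALSE]
    rxy <- Rc[eq$parents_i, eq$target_i]
    b <- if (lambda[k] == 0) {
      if (guard) ols_paths(Rx, rxy) else solve_small(Rx, rxy)
    } else {
      nr <- nrow(Rx)
      solve_small(Rx + diag(lambda[k], nr), rxy)
    }
    stats::setNames(b, eq$labels)
  }))
  coefs
}

#' Select the ridge parameter by K-fold cross-validation
#'
#' For each candidate value of the regularization parameter, the dataset is
#' split into K folds; Mode A weights, reliabilities and disattenuated
#' correlations are estimated on the training folds alone and the candidate
#' ridge coefficients are computed per structural equation. The out-of-fold
#' loss is evaluated on the structural (disattenuated) scale: validation rows
#' are standardized by training moments and scored with training weights,
#' their composite correlations are corrected for attenuation with the
#' training reliabilities, and the loss for an equation is the implied
#' out-of-sample residual variance \eqn{1 - 2\beta'r_v + \beta'R_v\beta}
#' accumulated over folds (weighted by fold size). When a validation fold is
#' too small to estimate correlations (fewer than 3 rows, e.g. leave-one-out),
#' the loss falls back to the squared prediction error of the validation
#' composite scores. Ties are broken toward the smallest (least biased) value.
#'
#' @param data indicator data matrix.
#' @param model a [plsc_model()].
#' @param K fold count in \code{[2, N]}; `K = N` gives leave-one-out
#'   (score-scale loss). Default 5.
#' @param grid candidate values, all >= 0 (default [default_lambda_grid()]).
#' @param seed RNG seed controlling the shuffled fold assignment (restored on
#'   exit); leave-one-out needs no shuffling.
#' @param per_equation select a separate value per endogenous equation
#'   (default) or one global value minimizing the summed error.
#' @param scheme,tol,max_iter passed to [estimate_weights()].
#' @return list with `lambda` (named vector per endogenous equation),
#'   `cv_error` (equations x grid matrix of mean out-of-fold losses),
#'   `grid`, `K`, and `folds_failed`.
#' @export
select_lambda <- function(data, model, K = 5L, grid = default_lambda_grid(),
                          seed = NULL, per_equation = TRUE,
                          scheme = "path", tol = 1e-6, max_iter = 300L) {
  X <- as.matrix(data)
  N <- nrow(X)
  if (is.null(K)) K <- 5L
  K <- min(K, N)
  if (K < 2 || K > N) stop("K must lie in [2, N]", call. = FALSE)
  if (!length(grid) || any(grid < 0))
    stop("lambda grid must be non-empty and nonnegative", call. = FALSE)
  grid <- sort(unique(as.numeric(grid)))
  layout <- pls_layout(model, colnames(X))
  eqs <- structural_equations(model)
  local_seed(seed)
  fold_id <- if (K == N) seq_len(N) else
    sample(rep_len(seq_len(K), N))
  if (min(tabulate(fold_id, K)) < 1)
    stop("empty cross-validation fold", call. = FALSE)
  if (N - max(tabulate(fold_id, K)) < 3)
    stop("training folds have fewer than 3 observations", call. = FALSE)
  err <- matrix(0, length(eqs), length(grid),
                dimnames = list(names(eqs), signif(grid, 6)))
  nval <- 0L
  folds_failed <- 0L
  for (k in seq_len(K)) {
    va <- which(fold_id == k)
    tr <- which(fold_id != k)
    fold_err <- tryCatch(
      cv_fold_error(X, tr, va, layout, eqs, grid, scheme, tol, max_iter),
      error = function(e) NULL)
    if (is.null(fold_err)) {
      folds_failed <- folds_failed + 1L
      next
    }
    err <- err + fold_err
    nval <- nval + length(va)
  }
  if (nval == 0L)
    stop("cross-validation failed in every fold", call. = FALSE)
  err <- err / nval
  if (per_equation) {
    lam <- apply(err, 1, function(e) {
      if (all(!is.finite(e))) grid[length(grid)] else grid[which.min(e)]
    })
  } else {
    tot <- colSums(err)
    lam_g <- if (all(!is.finite(tot))) grid[length(grid)] else grid[which.min(tot)]
    lam <- stats::setNames(rep(lam_g, length(eqs)), names(eqs))
  }
  list(lambda = lam, cv_error = err, grid = grid, K = K,
       folds_failed = folds_failed)
}

# Out-of-fold loss for one train/validation split, accumulated per equation
# over the lambda grid. Training folds provide weights, reliabilities and the
# ridge coefficient path; the validation fold is scored on the structural
# (disattenuated) scale when it is large enough to estimate correlations,
# otherwise on the composite score scale. Degenerate lambda values propagate
# as Inf (unsolvable); degenerate folds raise (caught by the caller).
cv_fold_error <- function(X, tr, va, layout, eqs, grid, scheme, tol, max_iter) {
  Xtr <- standardize_data(X[tr, , drop = FALSE])
  Str <- crossprod(Xtr) / (length(tr) - 1)
  fit <- consistent_core(Str, layout, scheme, tol, max_iter)
  ctr <- attr(Xtr, "center")
  scl <- attr(Xtr, "scale")
  Xva <- X[va, , drop = FALSE]
  Xva <- (Xva - rep(ctr, each = nrow(Xva))) / rep(scl, each = nrow(Xva))
  Yva <- Xva %*% fit$W
  nv <- nrow(Yva)
  latent_scale <- nv >= 3
  if (latent_scale) {
    sdv <- apply(Yva, 2, stats::sd)
    if (any(!is.finite(sdv) | sdv <= 0)) latent_scale <- FALSE
  }
  if (latent_scale) {
    Rv <- stats::cor(Yva) / sqrt(outer(fit$rho, fit$rho))
    diag(Rv) <- 1
  }
  err <- matrix(Inf, length(eqs), length(grid))
  for (j in seq_along(eqs)) {
    eq <- eqs[[j]]
    Rx <- fit$R[eq$parents_i, eq$parents_i, drop = FALSE]
    rxy <- fit$R[eq$parents_i, eq$target_i]
    ed <- eigen(Rx, symmetric = TRUE)
    tv <- drop(crossprod(ed$vectors, rxy))
    d <- outer(ed$values, grid, `+`)
    ok <- .colSums(abs(d) > 1e-12, nrow(d), ncol(d)) == nrow(d)
    if (!any(ok)) next
    B <- ed$vectors %*% (tv / d[, ok, drop = FALSE])
    if (latent_scale) {
      Rxv <- Rv[eq$parents_i, eq$parents_i, drop = FALSE]
      rxyv <- Rv[eq$parents_i, eq$target_i]
      # implied out-of-sample residual variance, 1 - 2 b'r_v + b' R_v b
      err[j, ok] <- nv * (1 - 2 * drop(crossprod(B, rxyv)) +
                            .colSums(B * (Rxv %*% B), nrow(B), ncol(B)))
    } else {
      pred <- Yva[, eq$parents_i, drop = FALSE] %*% B
      err[j, ok] <- .colSums((Yva[, eq$target_i] - pred)^2, nv, sum(ok))
    }
  }
  err
}

#' Fit a structural model by consistent PLS, optionally regularized
#'
#' Orchestrates the three estimation steps: (1) Mode A iterative weights and
#' composite correlations, (2) consistent reliabilities and disattenuation,
#' (3) per-equation least squares on the consistent correlations --- ordinary
#' (`method = "plsc"`) or ridge with a cross-validated regularization
#' parameter (`method = "regplsc"`). Equations are solved independently in
#' topological order; coefficients are standardized.
#'
#' @param data indicator data matrix (rows = observations). Alternatively pass
#'   `moments =` an exact indicator correlation matrix (e.g. a population
#'   `Sigma`) for analytic, population-level fits.
#' @param model a [plsc_model()].
#' @param method `"plsc"` (ordinary least squares, lambda = 0) or `"regplsc"`
#'   (ridge).
#' @param lambda optional fixed regularization value(s) for `"regplsc"`: a
#'   single number or a named vector per endogenous equation. When omitted,
#'   [select_lambda()] chooses it by cross-validation (data mode only).
#' @param K,grid,seed cross-validation controls, see [select_lambda()].
#' @param scheme,tol,max_iter weight-engine controls, see [estimate_weights()].
#' @param moments exact indicator correlation matrix in lieu of `data`.
#' @return object of class `plsc_fit`: `coefficients` (named over path
#'   labels), `lambda` (per equation), `rho_a` (see [reliabilities()]),
#'   `R_consistent` (a `plsc_consistent_cor`), `proxy_cor`, `weights`,
#'   `method`, `cv` (the [select_lambda()] result, when run).
#' @examples
#' pop <- build_population(list(N = 60, phi = 0.4, reliability = 0.8, r2 = 0.25))
#' fit <- plsc_fit(moments = pop$Sigma, model = pop$model, method = "plsc")
#' round(coef(fit), 3)
#' @export
plsc_fit <- function(data = NULL, model, method = c("plsc", "regplsc"),
                     lambda = NULL, K = NULL, grid = default_lambda_grid(),
                     seed = NULL, scheme = "path", tol = 1e-6, max_iter = 300L,
                     moments = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "plsc_model"))
  eqs <- structural_equations(model)
  if (!length(eqs)) stop("model has no endogenous latent variable", call. = FALSE)
  cv <- NULL
  if (!is.null(moments)) {
    S <- as.matrix(moments)
    if (is.null(colnames(S)))
      stop("moment matrix must carry indicator names", call. = FALSE)
    cols <- colnames(S)
    if (method == "regplsc" && is.null(lambda))
      stop("moments mode needs an explicit `lambda` for method \"regplsc\" ",
           "(cross-validation requires raw data)", call. = FALSE)
  } else {
    X <- as.matrix(data)
    if (is.null(colnames(X)))
      stop("data must carry indicator column names", call. = FALSE)
    X <- standardize_data(X)
    S <- crossprod(X) / (nrow(X) - 1)
    cols <- colnames(X)
    if (method == "regplsc" && is.null(lambda)) {
      cv <- select_lambda(X, model, K = K, grid = grid, seed = seed,
                          scheme = scheme, tol = tol, max_iter = max_iter)
      lambda <- cv$lambda
    }
  }
  lam <- expand_lambda(lambda, eqs, method)
  layout <- pls_layout(model, cols)
  core <- consistent_core(S, layout, scheme, tol, max_iter)
  Rc <- core$R
  dimnames(Rc) <- list(model$lv_names, model$lv_names)
  ev <- core$min_eig
  cons <- structure(list(R = Rc, pd = core$pd, min_eigenvalue = ev),
                    class = "plsc_consistent_cor")
  if (method == "plsc" && !core$pd)
    warning(sprintf(
      "consistent correlation matrix is not positive definite (smallest eigenvalue %.3g); least squares estimates may be unstable -- consider method \"regplsc\"",
      ev), call. = FALSE)
  coefs <- solve_paths_core(core$R, eqs, lam)
  W <- core$W
  dimnames(W) <- list(cols, model$lv_names)
  weights <- new_plsc_weights(list(W = W, iterations = core$iterations,
                                   converged = TRUE), model, cols, scheme)
  proxy <- core$proxy
  dimnames(proxy) <- list(model$lv_names, model$lv_names)
  structure(list(
    coefficients = coefs,
    lambda = stats::setNames(lam, names(eqs)),
    rho_a = data.frame(lv = model$lv_names, rho_a = core$rho,
                       valid = core$rho_valid, stringsAsFactors = FALSE),
    R_consistent = cons, proxy_cor = proxy, weights = weights,
    method = method, model = model, cv = cv,
    n = if (is.null(moments)) nrow(X) else NA_integer_
  ), class = "plsc_fit")
}

expand_lambda <- function(lambda, eqs, method) {
  if (method == "plsc") {
    if (!is.null(lambda) && any(lambda != 0))
      stop("method \"plsc\" implies lambda = 0", call. = FALSE)
    return(rep(0, length(eqs)))
  }
  if (is.null(lambda)) stop("lambda required", call. = FALSE)
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  if (length(lambda) == 1) return(rep(as.numeric(lambda), length(eqs)))
  if (!is.null(names(lambda))) {
    miss <- setdiff(names(eqs), names(lambda))
    if (length(miss))
      stop("lambda missing for equation(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    return(as.numeric(lambda[names(eqs)]))
  }
  if (length(lambda) != length(eqs))
    stop("lambda length must be 1 or the number of endogenous equations",
         call. = FALSE)
  as.numeric(lambda)
}

#' @export
coef.plsc_fit <- function(object, ...) object$coefficients

#' @export
print.plsc_fit <- function(x, ...) {
  cat(sprintf("Consistent PLS fit (method: %s)\n", x$method))
  cat("Path coefficients:\n")
  print(round(x$coefficients, 4))
  if (x$method == "regplsc")
    cat("lambda per equation:",
        paste(sprintf("%s = %.4g", names(x$lambda), x$lambda), collapse = ", "),
        "\n")
  cat("rho_A:", paste(sprintf("%s = %.3f", x$rho_a$lv, x$rho_a$rho_a),
                      collapse = ", "), "\n")
  if (!x$R_consistent$pd)
    cat("warning: consistent correlation matrix not positive definite\n")
  invisible(x)
}
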