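#' Draw a multivariate normal sample from a population model
#'
#' @param pop a [build_population()] result (or any list with a positive
#'   definite `Sigma` carrying indicator dimnames).
#' @param N number of rows.
#' @param seed RNG seed (restored on exit); a fixed seed gives an identical
#'   matrix across calls.
#' @return N x p indicator matrix with columns named after the indicators.
#' @export
generate_sample <- function(pop, N, seed = NULL) {
  Sigma <- pop$Sigma
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("population covariance matrix is not positive definite", call. = FALSE))
  local_seed(seed)
  p <- ncol(Sigma)
  X <- matrix(stats::rnorm(N * p), N, p) %*% ch
  colnames(X) <- colnames(Sigma)
  X
}

#' Mean absolute difference between estimates and true parameters
#'
#' \eqn{\mathrm{MAD} = \sum_j |\hat\theta_j - \theta_j| / P}, the
#' parameter-recovery metric aggregated over all structural paths.
#'
#' @param estimates,truth numeric vectors of equal length.
#' @return scalar mean absolute difference.
#' @examples
#' mad_error(c(0.5, 0.3), c(0.4, 0.5)) # 0.15
#' @export
mad_error <- function(estimates, truth) {
  if (length(estimates) != length(truth) || !length(truth))
    stop("estimates and truth must have equal, positive length", call. = FALSE)
  mean(abs(as.numeric(estimates) - as.numeric(truth)))
}

#' Run one design cell of the Monte Carlo study
#'
#' Draws samples from the cell's population until `reps` proper replications
#' are collected. A replication is proper when Mode A weight estimation
#' converges and the disattenuated latent correlation matrix is positive
#' definite (smallest eigenvalue > 1e-10); improper samples are discarded and
#' counted. Both estimators are fit to every proper sample: ordinary PLSc
#' (lambda = 0) and RegPLSc with a cross-validated regularization parameter.
#' With `B > 0`, bootstrap percentile confidence intervals are computed for
#' both methods on the same resample indices (common random numbers) with the
#' same resample refits (see [plsc_bootstrap()] for the refit rules), and the
#' per-path rejection indicator records whether the interval excludes zero ---
#' power for truly nonzero paths, type-I error for the true-zero path.
#'
#' @param cell list/one-row data.frame with `N`, `phi`, `reliability`, `r2`.
#' @param reps number of proper replications to keep (the study default is
#'   500; scaled-down runs commonly use 50--100).
#' @param B bootstrap resamples per replication (0 disables inference).
#' @param alpha significance level for the bootstrap intervals.
#' @param seed RNG seed for the whole cell (restored on exit).
#' @param grid,K cross-validation controls for RegPLSc, see [select_lambda()].
#' @param scheme,tol,max_iter weight-engine controls.
#' @param table population coefficient table, see [population_coefficients()].
#' @return object of class `plsc_cell_result`: the `cell`, `truth`
#'   coefficients, per-method mean `estimates` and `mad`, per-method per-path
#'   `rejection` proportions, `kept`, `discarded`, `boot_failed`, mean selected
#'   `lambda` per equation, and a per-replication long table `reps_table`.
#' @export
run_cell <- function(cell, reps = 500L, B = 200L, alpha = 0.05, seed = NULL,
                     grid = default_lambda_grid(), K = NULL, scheme = "path",
                     tol = 1e-6, max_iter = 300L,
                     table = population_coefficients()) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  pop <- build_population(cell, table)
  truth <- pop$coefficients
  model <- pop$model
  ch <- chol(pop$Sigma)
  cols <- colnames(pop$Sigma)
  layout <- pls_layout(model, cols)
  eqs <- structural_equations(model)
  P <- length(truth)
  nm <- names(truth)
  N <- cell$N
  methods <- c("plsc", "regplsc")

  local_seed(seed)
  est <- list(plsc = matrix(NA_real_, reps, P, dimnames = list(NULL, nm)),
              regplsc = matrix(NA_real_, reps, P, dimnames = list(NULL, nm)))
  rej <- list(plsc = matrix(NA, reps, P, dimnames = list(NULL, nm)),
              regplsc = matrix(NA, reps, P, dimnames = list(NULL, nm)))
  lam_kept <- matrix(NA_real_, reps, length(eqs),
                     dimnames = list(NULL, names(eqs)))
  boot_failed <- c(plsc = 0L, regplsc = 0L)
  kept <- 0L
  discarded <- 0L
  max_draws <- max(100L * reps, 500L)
  draws <- 0L
  while (kept < reps) {
    draws <- draws + 1L
    if (draws > max_draws)
      stop(sprintf("pathological cell: discard rate above 99%% (%d of %d draws improper)",
                   discarded, draws - 1L), call. = FALSE)
    X <- matrix(stats::rnorm(N * length(cols)), N) %*% ch
    colnames(X) <- cols
    core <- tryCatch(
      consistent_core(X, layout, scheme, tol, max_iter, from_data = TRUE),
      error = function(e) NULL)
    # proper solution: weights converged and the disattenuated correlation
    # matrix is positive definite, so the least squares step is well posed
    if (is.null(core) || !core$pd) {
      discarded <- discarded + 1L
      next
    }
    kept <- kept + 1L
    lam0 <- rep(0, length(eqs))
    est$plsc[kept, ] <- solve_paths_core(core$R, eqs, lam0, guard = FALSE)[nm]
    lam <- tryCatch(
      select_lambda(X, model, K = K, grid = grid, scheme = scheme,
                    tol = tol, max_iter = max_iter)$lambda,
      error = function(e) stats::setNames(lam0, names(eqs)))
    lam_kept[kept, ] <- lam
    est$regplsc[kept, ] <- solve_paths_core(core$R, eqs, lam)[nm]

    if (B > 0) {
      # both methods share resample indices and the Steps 1-2 refit; lambda
      # stays fixed at the full-sample cross-validated choice
      w_full <- lapply(seq_along(layout$blk), function(j)
        core$W[layout$blk[[j]], j])
      bdraw <- list(plsc = matrix(NA_real_, B, P, dimnames = list(NULL, nm)),
                    regplsc = matrix(NA_real_, B, P, dimnames = list(NULL, nm)))
      for (b in seq_len(B)) {
        ib <- sample.int(N, N, replace = TRUE)
        bc <- tryCatch(
          consistent_core(X[ib, , drop = FALSE], layout, scheme, tol,
                          max_iter, w_init = w_full, from_data = TRUE,
                          clamp_r = TRUE),
          error = function(e) NULL)
        if (is.null(bc)) next
        bdraw$plsc[b, ] <- tryCatch(
          solve_paths_core(bc$R, eqs, lam0, guard = TRUE)[nm],
          error = function(e) rep(NA_real_, P))
        # regplsc shares the resample's Steps 1-2; only lambda differs
        bdraw$regplsc[b, ] <- tryCatch(
          solve_paths_core(bc$R, eqs, lam)[nm], error = function(e) rep(NA_real_, P))
      }
      for (m in methods) {
        ok <- which(rowSums(!is.finite(bdraw[[m]])) == 0L)
        boot_failed[m] <- boot_failed[m] + (B - length(ok))
        if (length(ok) >= 2L) {
          kb <- bdraw[[m]][ok, , drop = FALSE]
          lo <- apply(kb, 2, stats::quantile, probs = alpha / 2, type = 7, names = FALSE)
          hi <- apply(kb, 2, stats::quantile, probs = 1 - alpha / 2, type = 7, names = FALSE)
          rej[[m]][kept, ] <- lo > 0 | hi < 0
        }
      }
    }
  }
  mad_rep <- vapply(methods, function(m)
    rowMeans(abs(est[[m]] - rep(truth, each = reps))), numeric(reps))
  mad_rep <- matrix(mad_rep, nrow = reps, dimnames = list(NULL, methods))
  reps_table <- data.frame(
    N = cell$N, phi = cell$phi, reliability = cell$reliability, r2 = cell$r2,
    rep = rep(seq_len(reps), times = 2),
    method = rep(methods, each = reps),
    mad = c(mad_rep[, "plsc"], mad_rep[, "regplsc"]),
    stringsAsFactors = FALSE)
  structure(list(
    cell = as.list(cell), truth = truth,
    estimates = rbind(plsc = colMeans(est$plsc), regplsc = colMeans(est$regplsc)),
    mad = colMeans(mad_rep),
    rejection = rbind(plsc = colMeans(rej$plsc, na.rm = TRUE),
                      regplsc = colMeans(rej$regplsc, na.rm = TRUE)),
    lambda_mean = colMeans(lam_kept),
    kept = kept, discarded = discarded, boot_failed = boot_failed,
    B = B, alpha = alpha, reps_table = reps_table
  ), class = "plsc_cell_result")
}

#' @export
print.plsc_cell_result <- function(x, ...) {
  cat(sprintf("Cell N = %d, phi = %g, reliability = %g, R2 = %g: %d kept, %d discarded\n",
              x$cell$N, x$cell$phi, x$cell$reliability, x$cell$r2,
              x$kept, x$discarded))
  cat(sprintf("  MAD: PLSc %.4f | RegPLSc %.4f\n",
              x$mad["plsc"], x$mad["regplsc"]))
  invisible(x)
}

#' Run a Monte Carlo study over a design grid
#'
#' Applies [run_cell()] to every design cell, deriving a deterministic
#' per-cell seed from the master seed, and aggregates parameter recovery and
#' rejection rates. The default grid is the full 48-cell factorial design of
#' [enumerate_cells()].
#'
#' @param cells design data.frame, see [enumerate_cells()].
#' @param reps,B,alpha,seed,grid,K,scheme,tol,max_iter see [run_cell()].
#' @param table population coefficient table.
#' @return object of class `plsc_study`: `cells`, the per-cell `results`
#'   list, a per-cell-and-method `summary` data.frame (MAD, per-path mean
#'   estimates and rejection proportions, discard counts), a per-replication
#'   long table `reps` suitable for external ANOVA, and `grand` (grand-mean
#'   MAD per method over all cells and replications).
#' @export
run_study <- function(cells = enumerate_cells(), reps = 500L, B = 200L,
                      alpha = 0.05, seed = 1L, grid = default_lambda_grid(),
                      K = NULL, scheme = "path", tol = 1e-6, max_iter = 300L,
                      table = population_coefficients()) {
  if (!nrow(cells)) stop("need at least one design cell", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  results <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    results[[i]] <- run_cell(cells[i, ], reps = reps, B = B, alpha = alpha,
                             seed = derive_seed(seed, i), grid = grid, K = K,
                             scheme = scheme, tol = tol, max_iter = max_iter,
                             table = table)
  }
  summary <- do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(c("plsc", "regplsc"), function(m) {
      row <- data.frame(N = r$cell$N, phi = r$cell$phi,
                        reliability = r$cell$reliability, r2 = r$cell$r2,
                        method = m, mad = unname(r$mad[m]),
                        kept = r$kept, discarded = r$discarded,
                        stringsAsFactors = FALSE)
      for (p in names(r$truth)) {
        row[[paste0("est_", p)]] <- r$estimates[m, p]
        row[[paste0("rej_", p)]] <- r$rejection[m, p]
      }
      row
    }))
  }))
  rownames(summary) <- NULL
  reps_tab <- do.call(rbind, lapply(results, `[[`, "reps_table"))
  grand <- stats::aggregate(mad ~ method, data = reps_tab, FUN = mean)
  structure(list(cells = cells, results = results, summary = summary,
                 reps = reps_tab, grand = grand,
                 options = list(reps = reps, B = B, alpha = alpha, seed = seed)),
            class = "plsc_study")
}

#' @export
print.plsc_study <- function(x, ...) {
  cat(sprintf("Monte Carlo study: %d cells x %d replications (B = %d)\n",
              nrow(x$cells), x$options$reps, x$options$B))
  cat("Grand-mean MAD per method:\n")
  print(x$grand, row.names = FALSE)
  invisible(x)
}
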