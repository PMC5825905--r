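#' Equal loading implied by a composite reliability target
#'
#' For a block of `p` reflective indicators sharing a common loading
#' \eqn{\lambda} on a unit-variance factor (standardized indicators), composite
#' reliability of the unweighted sum is
#' \deqn{\rho = (p\lambda)^2 / ((p\lambda)^2 + p(1-\lambda^2)).}
#' Solving for the loading gives
#' \eqn{\lambda = \sqrt{\rho / (p(1-\rho)+\rho)}}.
#'
#' @param rho target composite reliability, in (0, 1).
#' @param p number of indicators in the block, >= 2.
#' @return the common standardized loading, in (0, 1).
#' @examples
#' loading_for_reliability(0.8, 4) # sqrt(0.5)
#' @export
loading_for_reliability <- function(rho, p) {
  stopifnot(is.numeric(rho), length(rho) == 1, is.numeric(p), length(p) == 1)
  if (rho <= 0 || rho >= 1)
    stop("composite reliability must lie strictly between 0 and 1", call. = FALSE)
  if (p < 2) stop("need at least 2 indicators per block", call. = FALSE)
  sqrt(rho / (p * (1 - rho) + rho))
}

#' Common coefficient of two orthogonal predictors with a given R-squared
#'
#' Two mutually uncorrelated unit-variance predictors contributing equally to
#' a standardized outcome with explained variance `r2` each carry the
#' standardized coefficient \eqn{c = \sqrt{R^2/2}} (from \eqn{2c^2 = R^2}).
#' This is the identity that pins down the population coefficients of the
#' simulation model's second endogenous equation, whose two nonzero
#' predictors are orthogonal.
#'
#' @param r2 explained variance of the equation, in (0, 1).
#' @param k number of equally contributing orthogonal predictors.
#' @return the common standardized coefficient.
#' @examples
#' equal_orthogonal_coefficient(0.25) # 0.3536
#' @export
equal_orthogonal_coefficient <- function(r2, k = 2) {
  stopifnot(r2 > 0, r2 < 1, k >= 1)
  sqrt(r2 / k)
}

#' Latent correlation matrix implied by a standardized recursive system
#'
#' Given a recursive structural model with standardized latent variables
#' (all variances 1) and standardized path coefficients, computes the implied
#' latent correlation matrix by reduced-form path tracing: endogenous latent
#' variables are processed in topological order, their covariances with all
#' predecessors accumulate through the structural equations, and each
#' structural residual is given the variance that brings the total back to 1.
#'
#' @param model a [plsc_model()].
#' @param coefficients named numeric vector, one entry per path label in
#'   `model$paths`.
#' @return symmetric unit-diagonal correlation matrix over `model$lv_names`.
#' @examples
#' m <- simulation_model(phi = 0.4)
#' th <- c(gamma11 = 0.318, gamma12 = 0.279, gamma21 = 0.354, gamma22 = 0,
#'         gamma23 = 0.354, beta31 = 0.372, beta32 = 0.335)
#' implied_latent_correlations(m, th)["eta1", "xi1"] # 0.318 + 0.4 * 0.279
#' @export
implied_latent_correlations <- function(model, coefficients) {
  stopifnot(inherits(model, "plsc_model"))
  missing_lab <- setdiff(model$paths$label, names(coefficients))
  if (length(missing_lab))
    stop("missing coefficient(s) for path label(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  lvs <- model$lv_names
  L <- length(lvs)
  Phi <- diag(L)
  dimnames(Phi) <- list(lvs, lvs)
  for (key in names(model$exo_cor)) {
    p <- strsplit(key, "~~", fixed = TRUE)[[1]]
    Phi[p[1], p[2]] <- Phi[p[2], p[1]] <- model$exo_cor[[key]]
  }
  for (lv in model$order) {
    pa <- model$parents[[lv]]
    if (!length(pa)) next
    lab <- model$paths$label[model$paths$target == lv]
    b <- coefficients[lab[match(pa, model$paths$source[model$paths$target == lv])]]
    expl <- drop(t(b) %*% Phi[pa, pa, drop = FALSE] %*% b)
    if (expl >= 1)
      stop("invalid population: structural coefficients of `", lv,
           "` explain >= 100% of its variance (", signif(expl, 4), ")",
           call. = FALSE)
    # cov(lv, z) = sum_j b_j cov(parent_j, z); residual orthogonal to predecessors
    cv <- drop(Phi[, pa, drop = FALSE] %*% b)
    Phi[, lv] <- Phi[lv, ] <- cv
    Phi[lv, lv] <- 1
  }
  Phi
}

#' Design cells of the Monte Carlo study
#'
#' Enumerates the full factorial crossing of sample size, multicollinearity
#' level (correlation between the two collinear exogenous factors), composite
#' reliability, and the per-equation coefficient of determination. The default
#' levels give the 48-cell study design.
#'
#' @param N sample sizes.
#' @param phi multicollinearity levels.
#' @param reliability composite reliability levels.
#' @param r2 coefficient-of-determination levels.
#' @return data.frame with one row per cell and columns `N`, `phi`,
#'   `reliability`, `r2`; `N` varies slowest, `r2` fastest.
#' @examples
#' nrow(enumerate_cells()) # 48
#' @export
enumerate_cells <- function(N = c(30, 60, 120, 200), phi = c(0.4, 0.6, 0.8),
                            reliability = c(0.6, 0.8), r2 = c(0.25, 0.50)) {
  for (f in list(N, phi, reliability, r2))
    if (!length(f)) stop("every design factor needs at least one level", call. = FALSE)
  cells <- expand.grid(r2 = r2, reliability = reliability, phi = phi, N = N,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("N", "phi", "reliability", "r2")]
  rownames(cells) <- NULL
  cells
}

#' Population coefficient table for the simulation model
#'
#' Standardized population path coefficients of the six-latent-variable
#' simulation model for each crossing of multicollinearity (`phi`) and
#' explained variance (`r2`). Shipped as a plain-text fixture
#' (`extdata/population_coefficients.csv`); users may substitute their own
#' table with the same columns.
#'
#' @param path CSV file with columns `phi`, `r2`, `gamma11`, `gamma12`,
#'   `beta31`, `beta32`, `gamma21`, `gamma23`. Defaults to the packaged table.
#' @return data.frame of coefficients (the true-zero path `gamma22` is implied
#'   and added as a column of zeros).
#' @export
population_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "population_coefficients.csv",
                        package = "regplsc", mustWork = TRUE)
  tab <- utils::read.csv(path)
  need <- c("phi", "r2", "gamma11", "gamma12", "beta31", "beta32",
            "gamma21", "gamma23")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("coefficient table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(tab$gamma22)) tab$gamma22 <- 0
  tab
}

#' True path coefficients for one design cell
#'
#' @param cell one-row data.frame (or list) with `phi` and `r2`.
#' @param table coefficient table, see [population_coefficients()].
#' @return named vector over the simulation model's seven path labels, in
#'   the model's path order.
#' @export
cell_coefficients <- function(cell, table = population_coefficients()) {
  i <- which(abs(table$phi - cell$phi) < 1e-9 & abs(table$r2 - cell$r2) < 1e-9)
  if (length(i) != 1)
    stop(sprintf("no coefficient row for phi = %g, r2 = %g", cell$phi, cell$r2),
         call. = FALSE)
  lab <- c("gamma11", "gamma12", "gamma21", "gamma22", "gamma23",
           "beta31", "beta32")
  stats::setNames(as.numeric(table[i, lab]), lab)
}

#' Build the population model for a design cell
#'
#' Assembles the common-factor population implied by one design cell:
#' a 24 x 6 block-diagonal loading matrix with the equal loading solving the
#' composite-reliability identity, the latent correlation matrix implied by
#' the cell's standardized path coefficients, diagonal uniquenesses
#' \eqn{1-\lambda^2}, and the implied indicator correlation matrix
#' \eqn{\Sigma = \Lambda \Phi \Lambda' + \Theta} (unit diagonal).
#'
#' @param cell list/one-row data.frame with `N`, `phi`, `reliability`, `r2`.
#' @param table coefficient table, see [population_coefficients()].
#' @return object of class `plsc_population` with elements `Lambda`, `Phi`,
#'   `Theta`, `Sigma`, `model`, `coefficients`, `cell`.
#' @examples
#' pop <- build_population(list(N = 30, phi = 0.4, reliability = 0.8, r2 = 0.25))
#' all(eigen(pop$Sigma, symmetric = TRUE, only.values = TRUE)$values > 0)
#' @export
build_population <- function(cell, table = population_coefficients()) {
  model <- simulation_model(phi = cell$phi)
  theta <- cell_coefficients(cell, table)
  Phi <- implied_latent_correlations(model, theta)
  lam <- loading_for_reliability(cell$reliability, 4)
  L <- length(model$lv_names)
  p <- length(model$indicators)
  Lambda <- matrix(0, p, L, dimnames = list(model$indicators, model$lv_names))
  for (j in seq_len(L)) Lambda[model$blocks[[j]], j] <- lam
  Theta <- diag(1 - lam^2, p)
  dimnames(Theta) <- list(model$indicators, model$indicators)
  Sigma <- Lambda %*% Phi %*% t(Lambda) + Theta
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied indicator covariance matrix is not positive definite",
         call. = FALSE)
  structure(list(Lambda = Lambda, Phi = Phi, Theta = Theta, Sigma = Sigma,
                 model = model, coefficients = theta, cell = as.list(cell)),
            class = "plsc_population")
}

#' @export
print.plsc_population <- function(x, ...) {
  cat(sprintf(
    "Population model: %d indicators, %d latent variables (phi = %g, reliability = %g, R2 = %g)\n",
    nrow(x$Lambda), ncol(x$Lambda), x$cell$phi, x$cell$reliability, x$cell$r2))
  invisible(x)
}
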