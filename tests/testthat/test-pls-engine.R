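test_that("population moments yield the closed-form equal weights", {
  pop <- build_population(paper_cell(reliability = 0.8))
  w <- estimate_weights_moments(pop$Sigma, pop$model)
  expect_true(w$converged)
  # equal off-diagonals 0.5 force equal weights with w' S w = 1:
  # w = sqrt(1 / (4 (1 + 3 * 0.5))) = sqrt(0.1)
  for (lv in pop$model$lv_names)
    expect_equal(unname(w$weights[[lv]]), rep(sqrt(0.1), 4), tolerance = 1e-6)
})

test_that("exchangeable blocks get equal weights under every scheme", {
  m <- tiny_model()
  S <- diag(6)
  S[1:3, 1:3] <- block_sigma(sqrt(0.4), 3)
  S[4:6, 4:6] <- block_sigma(sqrt(0.4), 3)
  S[1:3, 4:6] <- 0.2
  S[4:6, 1:3] <- 0.2
  dimnames(S) <- list(c(m$blocks$xi, m$blocks$eta), c(m$blocks$xi, m$blocks$eta))
  for (sch in c("path", "centroid", "factorial")) {
    w <- estimate_weights_moments(S, m, scheme = sch)
    expect_equal(var(unname(w$weights$xi)), 0, tolerance = 1e-12)
    expect_equal(var(unname(w$weights$eta)), 0, tolerance = 1e-12)
  }
})

test_that("weight normalization, signs and fixed-point uniqueness hold", {
  pop <- build_population(paper_cell(phi = 0.6, reliability = 0.6, r2 = 0.5))
  X <- generate_sample(pop, 150, seed = 3)
  Xs <- standardize_data(X)
  S <- crossprod(Xs) / (nrow(X) - 1)
  w <- estimate_weights(X, pop$model)
  for (lv in pop$model$lv_names) {
    idx <- pop$model$blocks[[lv]]
    wv <- w$weights[[lv]]
    # unit composite variance
    expect_equal(drop(t(wv) %*% S[idx, idx] %*% wv), 1, tolerance = 1e-8)
    # positive weight sum
    expect_gt(sum(wv), 0)
  }
  # different starting values reach the same fixed point
  set.seed(9)
  w2 <- estimate_weights(X, pop$model,
                         w_init = lapply(pop$model$blocks, function(b) runif(4, 0.1, 1)))
  expect_equal(w2$W, w$W, tolerance = 1e-5)
})

test_that("permuting indicators within a block permutes weights identically", {
  pop <- build_population(paper_cell())
  X <- generate_sample(pop, 80, seed = 11)
  w <- estimate_weights(X, pop$model)
  perm <- c("x3", "x1", "x4", "x2")
  m2 <- pop$model
  m2$blocks$xi1 <- perm
  w2 <- estimate_weights(X, m2)
  expect_equal(w2$weights$xi1[c("x1", "x2", "x3", "x4")],
               w$weights$xi1, tolerance = 1e-8)
})

test_that("inner weighting schemes agree closely on the study populations", {
  pop <- build_population(paper_cell(phi = 0.8, reliability = 0.8, r2 = 0.5))
  X <- generate_sample(pop, 1e4, seed = 21)
  ws <- lapply(c("path", "centroid", "factorial"), function(s)
    estimate_weights(X, pop$model, scheme = s)$W)
  expect_lt(max(abs(ws[[1]] - ws[[2]])), 0.01)
  expect_lt(max(abs(ws[[1]] - ws[[3]])), 0.01)
})

test_that("composite scores are unit-variance linear combinations", {
  pop <- build_population(paper_cell())
  X <- generate_sample(pop, 200, seed = 5)
  w <- estimate_weights(X, pop$model)
  Y <- composite_scores(X, w)
  expect_identical(dim(Y), c(200L, 6L))
  expect_equal(unname(apply(Y, 2, var)), rep(1, 6), tolerance = 1e-8)

  # a block of one duplicated indicator reproduces the standardized indicator
  x <- rnorm(50)
  Xd <- cbind(x1 = x, x2 = x, x3 = x, y1 = rnorm(50), y2 = rnorm(50), y3 = rnorm(50))
  m <- tiny_model()
  wd <- estimate_weights(Xd, m)
  Yd <- composite_scores(Xd, wd)
  expect_equal(unname(Yd[, "xi"]), unname(standardize_data(Xd)[, "x1"]),
               tolerance = 1e-6)

  # population weights applied to a fresh large sample: variance tends to 1
  wpop <- estimate_weights_moments(pop$Sigma, pop$model)
  X2 <- generate_sample(pop, 1e5, seed = 6)
  Y2 <- composite_scores(X2, wpop)
  expect_equal(unname(apply(Y2, 2, var)), rep(1, 6), tolerance = 0.02)

  # all-zero weights are rejected
  wz <- wpop
  wz$weights$xi1[] <- 0
  expect_error(composite_scores(X2, wz), "zero")
})

test_that("proxy correlations attenuate the factor correlations", {
  pop <- build_population(paper_cell(phi = 0.4, reliability = 0.8))
  w <- estimate_weights_moments(pop$Sigma, pop$model)
  # population-level proxies: C = W' Sigma W
  Cp <- t(w$W) %*% pop$Sigma %*% w$W
  expect_equal(Cp["xi1", "xi2"], 0.4 * 0.8, tolerance = 1e-6)
  expect_lt(Cp["xi1", "xi2"], 0.4)

  # identical score columns correlate to one; constant columns error
  sc <- cbind(a = rnorm(20))
  expect_equal(proxy_correlations(cbind(sc, b = sc[, 1]))[1, 2], 1)
  expect_error(proxy_correlations(cbind(sc, b = rep(1, 20))), "constant")
})

test_that("degenerate data raise typed errors", {
  m <- tiny_model()
  X <- cbind(x1 = rnorm(30), x2 = rnorm(30), x3 = rep(1, 30),
             y1 = rnorm(30), y2 = rnorm(30), y3 = rnorm(30))
  expect_error(estimate_weights(X, m), class = "plsc_degenerate_data")
  Xok <- cbind(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30),
               y1 = rnorm(30), y2 = rnorm(30), y3 = rnorm(30))
  expect_error(estimate_weights(Xok, m, max_iter = 1L),
               class = "plsc_convergence_error")
  # the convergence condition carries the last iterate
  cond <- tryCatch(estimate_weights(Xok, m, max_iter = 1L),
                   error = function(e) e)
  expect_true(is.matrix(cond$weights))
})
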