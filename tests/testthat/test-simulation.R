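test_that("design-cell enumeration is the full factorial crossing", {
  cells <- enumerate_cells()
  expect_identical(nrow(cells), 48L)
  expect_identical(names(cells), c("N", "phi", "reliability", "r2"))
  expect_identical(nrow(unique(cells)), 48L)
  # N varies slowest, r2 fastest
  expect_identical(cells$N[1:12], rep(30, 12))
  expect_identical(cells$r2[1:2], c(0.25, 0.50))
  expect_identical(nrow(enumerate_cells(N = 30)), 12L)
  expect_identical(nrow(enumerate_cells(N = 60, phi = 0.4, reliability = 0.8,
                                        r2 = 0.5)), 1L)
  expect_error(enumerate_cells(N = numeric(0)), "at least one level")
})

test_that("sample generation is deterministic and distributionally correct", {
  pop <- build_population(paper_cell())
  X1 <- generate_sample(pop, 50, seed = 123)
  X2 <- generate_sample(pop, 50, seed = 123)
  expect_identical(X1, X2)
  expect_identical(dim(X1), c(50L, 24L))
  expect_identical(colnames(X1), colnames(pop$Sigma))
  X3 <- generate_sample(pop, 50, seed = 124)
  expect_false(identical(X1, X3))
  # non-PD population rejected
  bad <- pop
  bad$Sigma[1, 2] <- bad$Sigma[2, 1] <- 2
  expect_error(generate_sample(bad, 10, seed = 1), "positive definite")
})

test_that("mean absolute difference follows its definition", {
  expect_identical(mad_error(c(0.5, 0.3), c(0.4, 0.5)), 0.15)
  expect_identical(mad_error(1:5, 1:5), 0)
  # invariant to joint permutation
  set.seed(2)
  a <- rnorm(7); b <- rnorm(7); p <- sample(7)
  expect_equal(mad_error(a[p], b[p]), mad_error(a, b))
  expect_error(mad_error(1:3, 1:4), "equal")
  expect_error(mad_error(numeric(0), numeric(0)), "positive length")
})

test_that("run_cell keeps the requested replications and shares samples", {
  cell <- paper_cell(N = 60, phi = 0.4, reliability = 0.8, r2 = 0.5)
  r <- run_cell(cell, reps = 8, B = 0, seed = 42)
  expect_identical(r$kept, 8L)
  expect_gte(r$discarded, 0L)
  expect_identical(dim(r$estimates), c(2L, 7L))
  expect_identical(rownames(r$estimates), c("plsc", "regplsc"))
  # with B = 0 no rejection decisions are produced
  expect_true(all(is.nan(r$rejection)))
  # per-replication table covers both methods over the same replications
  expect_identical(nrow(r$reps_table), 16L)
  expect_identical(sort(unique(r$reps_table$method)), c("plsc", "regplsc"))
  # same master seed reproduces the cell exactly
  r2 <- run_cell(cell, reps = 8, B = 0, seed = 42)
  expect_identical(r$estimates, r2$estimates)
  expect_identical(r$reps_table$mad, r2$reps_table$mad)

  # with a single replication, the two methods differ only through shrinkage:
  # lambda = 0 equations coincide exactly
  r1 <- run_cell(cell, reps = 1, B = 0, seed = 7)
  lam <- r1$lambda_mean
  eq_of <- c(gamma11 = "eta1", gamma12 = "eta1", gamma21 = "eta2",
             gamma22 = "eta2", gamma23 = "eta2", beta31 = "eta3",
             beta32 = "eta3")
  for (p in colnames(r1$estimates)) {
    if (lam[eq_of[p]] == 0) {
      expect_equal(r1$estimates["plsc", p], r1$estimates["regplsc", p])
    }
  }
  expect_error(run_cell(cell, reps = 0), "reps")
})

test_that("discards are rare in the benign high-reliability cell", {
  r <- run_cell(paper_cell(N = 200, phi = 0.4, reliability = 0.8),
                reps = 40, B = 0, seed = 9)
  expect_identical(r$kept, 40L)
  expect_lte(r$discarded, 1L)
})

test_that("bootstrap decisions inside run_cell are reproducible", {
  cell <- paper_cell(N = 60, phi = 0.4, reliability = 0.8, r2 = 0.5)
  r1 <- run_cell(cell, reps = 2, B = 60, seed = 11)
  r2 <- run_cell(cell, reps = 2, B = 60, seed = 11)
  expect_identical(r1$rejection, r2$rejection)
  expect_true(all(r1$rejection %in% c(0, 0.5, 1)))
})

test_that("run_study aggregates cells into tidy tables and grand means", {
  cells <- enumerate_cells(N = 60, phi = c(0.4, 0.8), reliability = 0.8,
                           r2 = 0.25)
  st <- run_study(cells, reps = 4, B = 0, seed = 21)
  expect_identical(nrow(st$summary), 4L)      # 2 cells x 2 methods
  expect_identical(nrow(st$reps), 16L)        # 2 cells x 4 reps x 2 methods
  expect_identical(nrow(st$grand), 2L)
  expect_true(all(c("plsc", "regplsc") %in% st$grand$method))
  expect_true(all(st$summary$kept == 4L))
  # per-cell seeds derive deterministically from the master seed
  st2 <- run_study(cells, reps = 4, B = 0, seed = 21)
  expect_identical(st$grand, st2$grand)
  st3 <- run_study(cells, reps = 4, B = 0, seed = 22)
  expect_false(identical(st$grand, st3$grand))
  expect_error(run_study(cells, reps = 0), "reps")
  expect_error(run_study(cells[0, ], reps = 2), "at least one")
})

test_that("regularization stabilizes recovery under extreme collinearity", {
  # directional replication at reduced scale: in every extreme-collinearity
  # cell at N = 60, the regularized estimator recovers at least as well
  cells <- enumerate_cells(N = 60, phi = 0.8)
  st <- run_study(cells, reps = 30, B = 0, seed = 33)
  for (i in seq_len(nrow(cells))) {
    sub <- st$summary[st$summary$N == cells$N[i] &
                        st$summary$phi == cells$phi[i] &
                        st$summary$reliability == cells$reliability[i] &
                        st$summary$r2 == cells$r2[i], ]
    expect_lte(sub$mad[sub$method == "regplsc"],
               sub$mad[sub$method == "plsc"] + 0.01)
  }
})
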