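test_that("expression simulation is deterministic and matches the requested correlation", {
  X1 <- simulate_expression(5, corr_spec("independent"), m = 3, seed = 7)
  X2 <- simulate_expression(5, corr_spec("independent"), m = 3, seed = 7)
  expect_identical(X1, X2)
  expect_equal(dim(X1), c(5L, 3L))

  # Monte Carlo check of the exchangeable structure
  Xl <- simulate_expression(1e5, corr_spec("exchangeable", rho = 0.3),
                            m = 2, seed = 8)
  expect_equal(cor(Xl[, 1], Xl[, 2]), 0.3, tolerance = 0.01)
  expect_equal(unname(apply(Xl, 2, sd)), c(1, 1), tolerance = 0.02)

  # rho = 0 behaves as independent
  X0 <- simulate_expression(2e4, corr_spec("exchangeable", rho = 0),
                            m = 4, seed = 9)
  cm <- cor(X0)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.02)
})

test_that("identical seeds give bit-identical datasets", {
  scn <- scenario(30, 6, corr_spec("exchangeable", 0.1),
                  beta = beta_pattern(6, medium = 1), sigma = 3)
  d1 <- simulate_dataset(scn, seed = 42)
  d2 <- simulate_dataset(scn, seed = 42)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
})

test_that("phenotype model obeys the linear variance decomposition", {
  # null effects: phenotype independent of expression
  X <- simulate_expression(5e3, m = 3, seed = 1)
  y0 <- simulate_phenotype(X, rep(0, 3), sigma = 1, seed = 2)
  expect_lt(max(abs(cor(X, y0))), 0.05)
  expect_equal(var(y0), 1, tolerance = 0.05)

  # noiseless limit
  yn <- simulate_phenotype(X, c(2, 0, 0), sigma = 1e-8, seed = 3)
  expect_equal(yn, 2 * X[, 1], tolerance = 1e-6)

  # Var(Y) = beta' Sigma beta + sigma^2 = 2.6 + 9 = 11.6
  Xc <- simulate_expression(2e5, corr_spec("exchangeable", 0.3), m = 2,
                            seed = 4)
  yc <- simulate_phenotype(Xc, c(1, 1), sigma = 3, seed = 5)
  expect_equal(var(yc), 11.6, tolerance = 0.15)

  expect_error(simulate_phenotype(X, rep(0, 5)), "length")
})

test_that("theoretical R2 has the closed forms and monotonicities", {
  expect_identical(theoretical_r2(rep(0, 10), exch_spec(0.3), 2), 0)
  expect_equal(theoretical_r2(1, corr_spec("independent"), 1), 0.5)
  expect_equal(theoretical_r2(c(1, 1), corr_spec("exchangeable", 0.3), 3),
               2.6 / 11.6)

  # nondecreasing in each |beta_j|, nonincreasing in sigma
  withr::with_seed(11, {
    for (rep in 1:20) {
      m <- sample(2:6, 1)
      rho <- sample(c(0, 0.1, 0.3), 1)
      beta <- sample(0:3, m, replace = TRUE)
      sig <- sample(c(1, 3, 6), 1)
      base <- theoretical_r2(beta, exch_spec(rho), sig)
      j <- sample(m, 1)
      beta2 <- beta; beta2[j] <- beta2[j] + 1
      expect_gte(theoretical_r2(beta2, exch_spec(rho), sig), base)
      expect_lte(theoretical_r2(beta, exch_spec(rho), sig + 1), base)
    }
  })
})

test_that("null grid enumerates the fixed cross plus the empirical-structure cells", {
  grid <- null_scenario_grid()
  expect_equal(sum(grid$structure != "empirical"), 108)
  expect_equal(nrow(grid), 114)
  expect_true(all(grid$r2 == 0))
  expect_true(all(purrr::map_lgl(grid$beta, ~ all(.x == 0))))
  emp <- dplyr::filter(grid, structure == "empirical")
  expect_equal(nrow(emp), 6)
  expect_true(all(emp$m == 31))
  expect_setequal(emp$n, c(100, 500))

  # every row converts to an executable scenario
  scn_fixed <- as_scenario(grid[5, ])
  expect_s3_class(scn_fixed, "gsa_scenario")
  expect_true(is_null_scenario(scn_fixed))
  scn_emp <- as_scenario(emp[1, ])
  expect_equal(scn_emp$m, 31L)
  expect_equal(scn_emp$corr$kind, "empirical")
})

test_that("scenario grids round-trip through tab-delimited text", {
  grid <- dplyr::bind_rows(
    null_scenario_grid()[c(1, 60, 110), ],
    scenario_grid(n = 100, m = 10, rho = 0.3, sigma = 3,
                  patterns = list(c(small = 2, large = 1)))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scenario_grid(grid, path)
  back <- read_scenario_grid(path)
  expect_equal(back$label, grid$label)
  expect_equal(back$beta, grid$beta)
  expect_equal(back$r2, grid$r2)
})

test_that("empirical correlation estimation recovers the generating structure", {
  X <- simulate_expression(1e5, corr_spec("exchangeable", 0.3), m = 4,
                           seed = 21)
  est <- empirical_correlation(X)
  off <- est$matrix[upper.tri(est$matrix)]
  expect_equal(mean(off), 0.3, tolerance = 0.01)

  # orthogonalized mean-zero columns give the identity
  M <- matrix(rnorm(100 * 4), 100, 4)
  Z <- qr.Q(qr(sweep(M, 2, colMeans(M))))
  estz <- empirical_correlation(Z)
  expect_lt(max(abs(estz$matrix[upper.tri(estz$matrix)])), 1e-6)

  # duplicated column: off-diagonal 1, flagged but returned
  Xd <- cbind(a = X[1:50, 1], b = X[1:50, 1], c = X[1:50, 2])
  expect_warning(estd <- empirical_correlation(Xd), "Degenerate")
  expect_equal(estd$matrix["a", "b"], 1, tolerance = 1e-6)

  # constant probe is an error naming it
  Xc <- cbind(p1 = X[1:30, 1], p2 = rep(2, 30))
  expect_error(empirical_correlation(Xc), "p2")
})

test_that("the packaged 31-probe correlation fixture is a valid structure", {
  corr <- synthetic_pathway31()
  M <- corr$matrix
  expect_equal(dim(M), c(31L, 31L))
  expect_equal(unname(diag(M)), rep(1, 31))
  expect_equal(M, t(M))
  expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  # heterogeneous: a spread of within-set correlations, unlike exchangeable
  off <- M[upper.tri(M)]
  expect_gt(max(off), 0.5)
  expect_gt(sd(off), 0.1)

  # usable end to end
  X <- simulate_expression(200, corr, m = 31, seed = 3)
  expect_equal(dim(X), c(200L, 31L))
})

test_that("correlation specs validate and repair their inputs", {
  expect_error(corr_spec("exchangeable", rho = 1), "rho")
  expect_error(corr_spec("exchangeable", rho = -0.1), "rho")
  expect_error(corr_spec("empirical", matrix = matrix(c(1, 2, 0, 1), 2)),
               "symmetric")

  # an indefinite matrix with unit diagonal is repaired to PSD
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  spec <- corr_spec("empirical", matrix = bad)
  expect_gte(min(eigen(spec$matrix, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  expect_equal(unname(diag(spec$matrix)), rep(1, 3))
})
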