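test_that("a saturated signal gives near-complete power for every method", {
  # correlated probes with every effect large: the leading principal
  # component is the signal direction, so even PCA1 saturates
  scn <- scenario(100, 5, corr_spec("exchangeable", 0.3),
                  beta = rep(3, 5), sigma = 1)
  out <- run_scenario(scn, D = 30, B = 99, seed = 71)
  expect_true(all(out$applicable))
  expect_true(all(out$rate >= 0.9))
})

test_that("GMFE is reported not applicable rather than failing the run", {
  scn <- scenario(20, 50, corr_spec("exchangeable", 0.1), sigma = 1)
  out <- run_scenario(scn, D = 5, B = 49, methods = c("FM", "GMFE"),
                      seed = 72)
  gm <- dplyr::filter(out, method == "GMFE")
  expect_false(gm$applicable)
  expect_true(is.na(gm$rate))
  fm <- dplyr::filter(out, method == "FM")
  expect_true(fm$applicable)
  expect_false(is.na(fm$rate))
})

test_that("scenario runs are reproducible and independent of execution order", {
  grid <- null_scenario_grid() |>
    dplyr::filter(n == 20, m == 10, sigma == 1)
  a <- run_grid(grid, D = 8, B = 49, methods = "FM", seed = 73)
  b <- run_grid(grid[rev(seq_len(nrow(grid))), ], D = 8, B = 49,
                methods = "FM", seed = 73)
  expect_equal(dplyr::arrange(a, label), dplyr::arrange(b, label))
})

test_that("aggregation averages within method x n cells and flags empty cells", {
  scn <- scenario(30, 4, beta = beta_pattern(4, large = 2), sigma = 3)
  one <- run_scenario(scn, D = 10, B = 49, methods = c("FM", "KS"),
                      seed = 74)
  tab1 <- aggregate_rates(one)
  expect_equal(nrow(tab1), 2)
  expect_equal(sort(tab1$mean_rate), sort(one$rate))

  # mean over scenarios, invariant to row order
  scn2 <- scenario(30, 4, beta = beta_pattern(4, small = 1), sigma = 6)
  two <- dplyr::bind_rows(one, run_scenario(scn2, D = 10, B = 49,
                                            methods = c("FM", "KS"),
                                            seed = 75))
  t_fwd <- aggregate_rates(two)
  t_rev <- aggregate_rates(two[rev(seq_len(nrow(two))), ])
  expect_equal(tibble::as_tibble(t_fwd), tibble::as_tibble(t_rev))
  fm_cell <- dplyr::filter(t_fwd, method == "FM")
  expect_equal(fm_cell$n_scenarios, 2)
  expect_equal(fm_cell$mean_rate,
               mean(two$rate[two$method == "FM"]))

  # a cell where the method never applied is missing, not zero
  na_out <- run_scenario(scenario(20, 50, sigma = 1), D = 3, B = 19,
                         methods = "GMFE", seed = 76)
  t_na <- aggregate_rates(na_out)
  expect_equal(t_na$n_scenarios, 0)
  expect_true(is.nan(t_na$mean_rate))
})

test_that("asymptotic FM agrees with permutation FM when m = 1", {
  # at m = 1 there is no combination step: the chi-square inversion
  # returns the exact probe p, so the two modes reject identically often
  scn <- scenario(50, 1, beta = 1, sigma = 2, label = "m1check")
  asym <- run_scenario_asymptotic_fm(scn, D = 60, seed = 77)
  perm <- run_scenario(scn, D = 60, B = 400, methods = "FM", seed = 77)
  expect_equal(asym$rate, perm$rate, tolerance = 0.05)
  expect_equal(asym$mode, "asymptotic")
})

test_that("expression, phenotype and GMT files parse and round-trip", {
  X <- simulate_expression(5, m = 3, seed = 81)
  rownames(X) <- paste0("s", 1:5)
  ef <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample = rownames(X), X, check.names = FALSE),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_expression(ef)
  expect_equal(back, X)

  # probes-in-rows layout
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(probe = colnames(X), t(X), check.names = FALSE),
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(tf, transpose = TRUE), X)

  pf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tic50", paste(rownames(X), seq(0.1, 0.5, 0.1),
                                     sep = "\t")), pf)
  y <- read_phenotype(pf)
  expect_equal(unname(y), seq(0.1, 0.5, 0.1))
  expect_named(y, rownames(X))

  al <- align_samples(X[5:1, ], y)
  expect_equal(al$y[1], y["s5"])

  # unmatched sample identifiers are named in the error
  names(y)[2] <- "stranger"
  expect_error(align_samples(X, y), "stranger")

  gf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2", "setB\tpathway B\tg2\tg3\tg4"), gf)
  sets <- read_gmt(gf)
  expect_equal(sets$set, c("setA", "setB"))
  expect_equal(sets$members[[1]], c("g1", "g2"))
  writeLines(c("setA\tdesc\tg1", "broken"), gf)
  expect_error(read_gmt(gf), "line 2")

  rf <- withr::local_tempfile(fileext = ".csv")
  rows <- tibble::tibble(a = c(1.123456789, 2), b = c("x", "y"))
  write_results(rows, rf)
  expect_equal(readr::read_csv(rf, show_col_types = FALSE), rows)
})

test_that("gene-set screening separates a planted set from a null set", {
  d <- planted_dataset(n = 80, m = 12, k = 4, effect = 2, sigma = 2,
                       seed = 91)
  sets <- list(hit = colnames(d$X)[1:4], decoy = colnames(d$X)[5:12])
  res <- screen_gene_sets(d$X, d$y, sets, B = 199,
                          methods = c("FM", "GMRE"), seed = 92)
  expect_equal(nrow(res), 4)
  expect_true(all(res$B == 199))
  fm <- dplyr::filter(res, method == "FM")
  expect_lt(fm$p_perm[fm$set == "hit"], fm$p_perm[fm$set == "decoy"])
  expect_lt(fm$p_perm[fm$set == "hit"], 0.05)

  # missing members dropped with a warning; empty sets give missing rows
  sets2 <- list(partial = c(colnames(d$X)[1:2], "ghost1"),
                absent = c("ghost2", "ghost3"))
  warns <- capture_warnings(
    res2 <- screen_gene_sets(d$X, d$y, sets2, B = 49, methods = "FM",
                             seed = 93)
  )
  expect_true(any(grepl("1 of 3 probes absent", warns)))
  expect_true(any(grepl("no probes", warns)))
  expect_equal(res2$m[res2$set == "partial"], 2L)
  expect_true(is.na(res2$p_perm[res2$set == "absent"]))

  # BH adjustment is added per method across sets
  res3 <- screen_gene_sets(d$X, d$y, sets, B = 99, methods = "FM",
                           seed = 94, adjust_bh = TRUE)
  expect_true("p_adjusted" %in% names(res3))
  expect_equal(res3$p_adjusted,
               p.adjust(res3$p_perm, "BH"))
})

test_that("single-probe sets collapse FM and GMFE to near-identical inference", {
  d <- planted_dataset(n = 50, m = 3, k = 1, effect = 1, sigma = 1,
                       seed = 95)
  sets <- list(solo = colnames(d$X)[1])
  res <- screen_gene_sets(d$X, d$y, sets, B = 999,
                          methods = c("FM", "GMFE"), seed = 96)
  expect_equal(res$p_perm[res$method == "FM"],
               res$p_perm[res$method == "GMFE"], tolerance = 1e-12)
})
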