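# Shared helpers for the test suite. All fixtures are generated in code.

exch_spec <- function(rho) {
  if (rho == 0) corr_spec("independent") else corr_spec("exchangeable", rho = rho)
}

# A small dataset with a planted signal in the first `k` probes.
planted_dataset <- function(n = 60, m = 10, k = 3, effect = 2, sigma = 3,
                            rho = 0, seed = 101) {
  X <- simulate_expression(n, exch_spec(rho), m = m, seed = seed)
  beta <- c(rep(effect, k), rep(0, m - k))
  y <- simulate_phenotype(X, beta, sigma = sigma, seed = seed + 1)
  list(X = X, y = y, beta = beta)
}

# Exact permutation p-value computed independently of the package's
# vectorized engine: enumerates permutations by hand and evaluates the
# statistic through the exported scalar functions.
oracle_exhaustive_p <- function(X, y, stat_fun) {
  perms <- NULL
  gen <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in gen(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  idx <- gen(seq_along(y))
  obs <- stat_fun(X, y)
  stats <- vapply(idx, function(ix) stat_fun(X, y[ix]), numeric(1))
  mean(stats >= obs)
}

# Per-method statistic evaluated through the exported scalar interface
# (used as the independent route in oracle comparisons).
scalar_stat_fun <- function(method) {
  switch(method,
    KS = function(X, y) ks_dplus(probe_pvalues(X, y))$statistic,
    FM = function(X, y) fisher_statistic(probe_pvalues(X, y))$statistic,
    SM = function(X, y) stouffer_statistic(probe_pvalues(X, y))$statistic,
    TS = function(X, y) tail_strength(probe_pvalues(X, y))$statistic,
    MTS = function(X, y) modified_tail_strength(probe_pvalues(X, y))$statistic,
    GMFE = function(X, y) gmfe_test(X, y)$statistic,
    GMRE = function(X, y) gmre_score(X, y)$statistic,
    PCA1 = function(X, y) pca_test(X, y, "first")$statistic,
    `PCA1.5` = function(X, y) pca_test(X, y, "top5")$statistic,
    PCA80 = function(X, y) pca_test(X, y, "var80")$statistic
  )
}

binom99_halfwidth <- function(p, n) 2.576 * sqrt(p * (1 - p) / n)
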