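#' Per-probe F-test of association with a continuous phenotype
#'
#' Tests a single probe's expression against the phenotype via the Pearson
#' correlation `r`: the statistic is `F = (n - 2) r^2 / (1 - r^2)`, with
#' the p-value taken from the upper tail of the F distribution with 1 and
#' `n - 2` degrees of freedom. This is identical to the two-sided t-test on
#' the slope of the simple linear regression of `y` on `x`. A constant
#' input (zero variance in `x` or `y`) is the degenerate case: `r = 0`,
#' `p = 1`, with a warning. P-values are floored at `1e-300` so that
#' downstream log transforms stay finite.
#'
#' @param x Expression vector for one probe.
#' @param y Continuous phenotype vector, same length as `x` (n >= 4).
#' @param probe Optional probe identifier carried into the result.
#' @return A one-row tibble with columns `probe`, `r`, `statistic`, `df1`,
#'   `df2`, `p_value`.
#' @examples
#' x <- rnorm(20); y <- 0.5 * x + rnorm(20)
#' probe_f_test(x, y)
#' @export
probe_f_test <- function(x, y, probe = NA_character_) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 4) abort("Need at least 4 observations for the probe F-test.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input to probe F-test; returning r = 0, p = 1.")
    r <- 0
  } else {
    r <- cor(x, y)
  }
  f <- if (abs(r) >= 1) Inf else (n - 2) * r^2 / (1 - r^2)
  p <- max(pf(f, 1, n - 2, lower.tail = FALSE), .P_FLOOR)
  tibble::tibble(probe = probe, r = r, statistic = f,
                 df1 = 1, df2 = n - 2, p_value = p)
}

#' Per-probe association p-values for a gene set
#'
#' Applies the probe F-test to every column of the expression matrix,
#' preserving probe order. This vector of p-values is the input to the
#' p-value combination statistics ([ks_dplus()], [fisher_statistic()],
#' [stouffer_statistic()], [tail_strength()], [modified_tail_strength()]).
#'
#' @param X Samples x probes expression matrix or numeric data frame.
#' @param y Continuous phenotype vector aligned to the rows of `X`.
#' @return Named numeric vector of `ncol(X)` p-values in probe order.
#' @examples
#' X <- simulate_expression(30, m = 5, seed = 1)
#' y <- simulate_phenotype(X, beta = c(2, rep(0, 4)), seed = 2)
#' probe_pvalues(X, y)
#' @export
probe_pvalues <- function(X, y) {
  X <- as_expression_matrix(X)
  if (nrow(X) != length(y)) {
    abort(sprintf("X has %d samples but y has length %d.",
                  nrow(X), length(y)))
  }
  if (nrow(X) < 4) abort("Need at least 4 samples.")
  p <- drop(probe_p_matrix(X, matrix(y, ncol = 1)))
  names(p) <- colnames(X)
  p
}

# Vectorized probe p-values for many phenotype columns at once.
# X: n x m; Ymat: n x (B+1). Returns m x (B+1) matrix of upper-tail
# F(1, n-2) p-values of the per-probe Pearson correlations. Constant
# columns (in X or Ymat) yield p = 1 for the affected entries.
probe_p_matrix <- function(X, Ymat) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  xs <- sqrt(colSums(Xc^2))
  Yc <- sweep(Ymat, 2, colMeans(Ymat))
  ys <- sqrt(colSums(Yc^2))
  denom <- outer(xs, ys)
  r <- crossprod(Xc, Yc)
  r <- ifelse(denom > 0, r / denom, 0)
  r2 <- pmin(r^2, 1)
  f <- (n - 2) * r2 / pmax(1 - r2, .Machine$double.xmin)
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  matrix(pmax(p, .P_FLOOR), nrow = ncol(X))
}
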