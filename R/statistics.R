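new_gsa_stat <- function(method, statistic, p_asymptotic = NA_real_,
                         df = NA_real_, m = NA_integer_, note = NULL) {
  structure(
    list(method = method, statistic = statistic,
         orientation = "larger-is-more-significant",
         p_asymptotic = p_asymptotic, df = df, m = m, note = note),
    class = "gsa_stat"
  )
}

#' @export
print.gsa_stat <- function(x, ...) {
  cat(sprintf("<gene-set statistic> %s = %.6g", x$method, x$statistic))
  if (!is.na(x$p_asymptotic)) {
    cat(sprintf(", asymptotic p = %.4g (df = %s)", x$p_asymptotic,
                paste(x$df, collapse = ", ")))
  } else {
    cat(" (significance by permutation)")
  }
  if (!is.null(x$note)) cat("\n  note:", x$note)
  cat("\n")
  invisible(x)
}

#' @method tidy gsa_stat
#' @export
tidy.gsa_stat <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic,
    df = if (all(is.na(x$df))) NA_real_ else x$df[1],
    p_asymptotic = x$p_asymptotic, m = x$m
  )
}

check_pvector <- function(p, positive = TRUE) {
  if (length(p) < 1) abort("Need at least one p-value.")
  if (anyNA(p)) abort("P-values must not be NA.")
  if (positive && any(p <= 0)) abort("P-values must be strictly positive.")
  if (any(p > 1)) abort("P-values must not exceed 1.")
  as.numeric(p)
}

#' One-sided Kolmogorov-Smirnov gene-set statistic
#'
#' Measures whether the probe p-values are smaller than expected under a
#' Uniform(0, 1) null: `d+ = max_i (i/m - p_(i))` over the ordered
#' p-values, floored at 0. Large values indicate an excess of small
#' p-values. No asymptotic p-value is attached; significance is assessed
#' by phenotype permutation (see [empirical_pvalue()]).
#'
#' @param p Vector of m probe p-values in (0, 1].
#' @return A `gsa_stat` object.
#' @examples
#' ks_dplus(c(0.1, 0.2, 0.3, 0.9))  # d+ = 0.45
#' @export
ks_dplus <- function(p) {
  p <- check_pvector(p, positive = FALSE)
  m <- length(p)
  d <- max(seq_len(m) / m - sort(p))
  new_gsa_stat("KS", max(d, 0), m = m)
}

#' Fisher's method for combining probe p-values
#'
#' The combination statistic `-2 * sum(log(p_i))`, distributed chi-squared
#' with `2m` degrees of freedom when the m p-values are independent and
#' Uniform(0, 1) under the null. The attached asymptotic p-value assumes
#' that independence; for correlated probes use the permutation p-value
#' instead, which is exactly why the permutation engine exists.
#'
#' @inheritParams ks_dplus
#' @return A `gsa_stat` with the chi-squared asymptotic p-value.
#' @examples
#' fisher_statistic(c(0.05, 0.5))
#' @export
fisher_statistic <- function(p) {
  p <- check_pvector(p)
  m <- length(p)
  stat <- -2 * sum(log(p))
  new_gsa_stat("FM", stat, p_asymptotic = pchisq(stat, 2 * m,
                                                 lower.tail = FALSE),
               df = 2 * m, m = m, note = "asymptotic p assumes independence")
}

#' Stouffer's method for combining probe p-values
#'
#' Transforms each p-value to a normal deviate `z_i = qnorm(1 - p_i)` and
#' sums: the statistic is `sum(z_i) / sqrt(m)`, standard normal under
#' independence, tested one-sided against large values. P-values equal to
#' 1 are clipped just below 1 so the deviate stays finite.
#'
#' @inheritParams ks_dplus
#' @return A `gsa_stat` with the one-sided normal asymptotic p-value.
#' @examples
#' stouffer_statistic(rep(0.025, 4))
#' @export
stouffer_statistic <- function(p) {
  p <- check_pvector(p)
  if (any(p >= 1)) {
    inform("Stouffer: p-values equal to 1 clipped below 1.")
    p <- pmin(p, .P_CEIL)
  }
  m <- length(p)
  stat <- sum(qnorm(p, lower.tail = FALSE)) / sqrt(m)
  new_gsa_stat("SM", stat, p_asymptotic = pnorm(stat, lower.tail = FALSE),
               m = m, note = "asymptotic p assumes independence")
}

#' Tail strength of a set of probe p-values
#'
#' `TS = (1/m) * sum_k [1 - p_(k) * (m + 1) / k]` over the ordered
#' p-values. Each ordered p-value is compared with its null expectation
#' `k / (m + 1)`; the statistic has expectation 0 under iid Uniform(0, 1)
#' p-values and is positive when ordered p-values run smaller than
#' expected.
#'
#' @inheritParams ks_dplus
#' @return A `gsa_stat` (permutation significance).
#' @examples
#' tail_strength(c(0.1, 0.4))  # 0.55
#' @export
tail_strength <- function(p) {
  p <- check_pvector(p, positive = FALSE)
  m <- length(p)
  k <- seq_len(m)
  stat <- mean(1 - sort(p) * (m + 1) / k)
  new_gsa_stat("TS", stat, m = m)
}

#' Modified tail strength on the -log scale
#'
#' A log-scale analogue of [tail_strength()]: with `X_i = -log(p_(i))` (so
#' `X_1 >= ... >= X_m`) and `e_i = sum_{j=i}^{m} 1/j` — the expectation of
#' the i-th largest of m standard exponentials — the statistic compares
#' each ordered `-log` p-value with its null expectation. Two variants are
#' provided, both with expectation 0 under iid Uniform(0, 1) p-values:
#'
#' * `"ratio"` (default): `MTS = (1/m) * sum_i (X_i / e_i - 1)`, which
#'   normalizes each order statistic by its expectation, mirroring how
#'   tail strength rescales each `p_(k)` by `k/(m+1)`;
#' * `"literal"`: `MTS = (1/m) * sum_i (X_i - e_i)`. Because
#'   `sum_i X_i = sum_i -log(p_i)` does not depend on the ordering, this
#'   variant is an affine function of Fisher's statistic and therefore
#'   yields permutation p-values identical to [fisher_statistic()]; it is
#'   exposed for completeness but the ratio form is the distinct test.
#'
#' @inheritParams ks_dplus
#' @param variant `"ratio"` (default) or `"literal"`.
#' @return A `gsa_stat` (permutation significance).
#' @examples
#' modified_tail_strength(c(0.05, 0.5))
#' @export
modified_tail_strength <- function(p, variant = c("ratio", "literal")) {
  variant <- match.arg(variant)
  p <- check_pvector(p)
  m <- length(p)
  x <- -log(sort(p))                    # decreasing: largest exponential first
  e <- rev(cumsum(1 / rev(seq_len(m)))) # e_i = sum_{j=i}^m 1/j
  stat <- if (variant == "ratio") mean(x / e - 1) else mean(x - e)
  new_gsa_stat("MTS", stat, m = m, note = paste0("variant = ", variant))
}

#' Global fixed-effects gene-set test
#'
#' Fits the ordinary least-squares regression of the phenotype on all m
#' probe columns jointly (plus intercept) and tests the null that every
#' slope is zero with the overall F statistic on `(m, n - m - 1)` degrees
#' of freedom. Only estimable when `m <= n - 2`; larger sets raise a
#' non-estimability error, which scenario runners report as "not
#' applicable".
#'
#' @param X Samples x probes expression matrix or numeric data frame.
#' @param y Continuous phenotype aligned to rows of `X`.
#' @return A `gsa_stat` with the exact F p-value.
#' @examples
#' X <- simulate_expression(30, m = 3, seed = 1)
#' y <- simulate_phenotype(X, beta = c(1, 0, 0), seed = 2)
#' gmfe_test(X, y)
#' @export
gmfe_test <- function(X, y) {
  X <- as_expression_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (nrow(X) != length(y)) abort("X and y dimensions disagree.")
  if (m > n - 2) {
    abort(
      sprintf("GMFE is non-estimable: m = %d probes with only n = %d samples.",
              m, n),
      class = "gsaperm_nonestimable"
    )
  }
  st <- gmfe_stats(X, matrix(y, ncol = 1))
  new_gsa_stat("GMFE", st, p_asymptotic = pf(st, m, n - m - 1,
                                             lower.tail = FALSE),
               df = c(m, n - m - 1), m = m)
}

# Overall regression F statistics of each column of Ymat on X.
gmfe_stats <- function(X, Ymat) {
  n <- nrow(X); m <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Ymat, 2, colMeans(Ymat))
  Q <- qr.Q(qr(Xc))
  tss <- colSums(Yc^2)
  ssreg <- colSums(crossprod(Q, Yc)^2)
  rss <- pmax(tss - ssreg, 0)
  (ssreg / m) / (rss / (n - m - 1))
}

#' Global random-effects score statistic
#'
#' Score test of the variance component in the random-effects model where
#' the phenotype is a linear function of all probe effects drawn from a
#' common mean-zero distribution; under the null that the effect variance
#' is zero the phenotype is unrelated to expression. With centered
#' residuals `r = y - mean(y)` and column-centered expression `X`, the
#' statistic is the scale-free quadratic form
#' `Q = (r' X X' r) / (r' r)`. `Q` is invariant to shifting or rescaling
#' `y` and to orthogonal rotation of the probe columns, and any monotone
#' rescaling of it yields the same permutation p-value, which is how its
#' significance is assessed (no asymptotic p is attached).
#'
#' @inheritParams gmfe_test
#' @return A `gsa_stat` (permutation significance).
#' @examples
#' X <- simulate_expression(30, m = 10, seed = 1)
#' y <- simulate_phenotype(X, beta = rep(0, 10), seed = 2)
#' gmre_score(X, y)
#' @export
gmre_score <- function(X, y) {
  X <- as_expression_matrix(X)
  if (nrow(X) != length(y)) abort("X and y dimensions disagree.")
  if (nrow(X) < 3) abort("Need at least 3 samples.")
  if (sd(y) == 0) abort("Phenotype has zero variance.")
  st <- gmre_stats(X, matrix(y, ncol = 1))
  new_gsa_stat("GMRE", st, m = ncol(X))
}

gmre_stats <- function(X, Ymat) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Ymat, 2, colMeans(Ymat))
  colSums(crossprod(Xc, Yc)^2) / colSums(Yc^2)
}

#' Principal-component regression gene-set tests
#'
#' Computes principal components of the column-centered, column-scaled
#' expression submatrix (correlation-matrix PCA) and tests the phenotype
#' regression on the top components with a likelihood-ratio chi-square:
#' `LRT = n * log(RSS0 / RSS_k)` comparing `y ~ PC_1..PC_k` against the
#' intercept-only model, on k degrees of freedom. The number of components
#' k is chosen by the selector:
#'
#' * `"first"` (PCA1): k = 1;
#' * `"top5"` (PCA1.5): k = min(5, m, n - 2);
#' * `"var80"` (PCA80): smallest k whose cumulative explained variance
#'   reaches 80%, capped at min(m, n - 2) so the regression stays
#'   estimable.
#'
#' Zero-variance probe columns are dropped with a warning before the PCA;
#' if every column is constant an error is raised.
#'
#' @inheritParams gmfe_test
#' @param selector `"first"`, `"top5"` or `"var80"`.
#' @return A `gsa_stat` with the chi-squared asymptotic p-value on k df.
#' @examples
#' X <- simulate_expression(50, corr_spec("exchangeable", 0.3), m = 10,
#'                          seed = 1)
#' y <- simulate_phenotype(X, beta_pattern(10, medium = 2), seed = 2)
#' pca_test(X, y, "var80")
#' @export
pca_test <- function(X, y, selector = c("first", "top5", "var80")) {
  selector <- match.arg(selector)
  X <- as_expression_matrix(X)
  if (nrow(X) != length(y)) abort("X and y dimensions disagree.")
  if (nrow(X) < 4) abort("Need at least 4 samples.")
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) abort("All probe columns have zero variance.")
  if (any(sds == 0)) {
    warn(sprintf("Dropping %d zero-variance probe column(s) before PCA.",
                 sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  pca <- pca_basis(X)
  k <- pca_k(pca, selector, nrow(X))
  st <- pca_lrt_stats(pca, matrix(y, ncol = 1), k)
  method <- c(first = "PCA1", top5 = "PCA1.5", var80 = "PCA80")[[selector]]
  new_gsa_stat(method, st, p_asymptotic = pchisq(st, k, lower.tail = FALSE),
               df = k, m = ncol(X),
               note = sprintf("k = %d principal component(s)", k))
}

# Orthonormal PC score basis of the standardized matrix, with explained
# variance fractions. U's columns span successive principal subspaces.
pca_basis <- function(X) {
  Xs <- scale(X)
  sv <- svd(Xs, nv = 0)
  rank <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  list(U = sv$u[, seq_len(rank), drop = FALSE],
       varfrac = sv$d[seq_len(rank)]^2 / sum(sv$d^2), rank = rank)
}

pca_k <- function(pca, selector, n) {
  cap <- max(min(pca$rank, n - 2), 1)
  switch(selector,
    first = 1L,
    top5 = as.integer(min(5, cap)),
    var80 = {
      cum <- cumsum(pca$varfrac)
      k <- which(cum >= 0.80 - 1e-12)[1]
      if (is.na(k)) k <- pca$rank
      as.integer(min(k, cap))
    }
  )
}

# LRT statistics n*log(RSS0/RSSk) for each phenotype column of Ymat
# regressed on the first k PC scores.
pca_lrt_stats <- function(pca, Ymat, k) {
  n <- nrow(Ymat)
  Yc <- sweep(Ymat, 2, colMeans(Ymat))
  tss <- colSums(Yc^2)
  proj <- crossprod(pca$U[, seq_len(k), drop = FALSE], Yc)
  rss <- pmax(tss - colSums(proj^2), .Machine$double.xmin)
  n * log(tss / rss)
}
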