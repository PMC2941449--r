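#' Between-probe correlation specifications
#'
#' A `corr_spec` describes the correlation structure of expression values
#' within a gene set, used by [simulate_expression()] and
#' [theoretical_r2()]. Three kinds are supported:
#'
#' * `"independent"`: identity correlation (no correlation between probes);
#' * `"exchangeable"`: every pair of probes shares one common correlation
#'   `rho` in `[0, 1)`, variances are 1;
#' * `"empirical"`: an arbitrary correlation matrix, typically estimated
#'   from real expression data with [empirical_correlation()]. The matrix is
#'   validated (symmetric, unit diagonal) and repaired to be positive
#'   semi-definite by clipping eigenvalues below `repair_tol` and rescaling
#'   back to unit diagonal.
#'
#' @param kind One of `"independent"`, `"exchangeable"`, `"empirical"`.
#' @param rho Common pairwise correlation (exchangeable only), in `[0, 1)`.
#' @param matrix Square correlation matrix (empirical only).
#' @param repair_tol Eigenvalues of an empirical matrix below this value are
#'   clipped up to it before rescaling; an eigenvalue that cannot be
#'   repaired raises an error naming it.
#' @return An object of class `gsa_corr_spec` with fields `kind`, `rho`,
#'   `matrix`, `m` (fixed set size for empirical, `NA` otherwise).
#' @examples
#' corr_spec("exchangeable", rho = 0.3)
#' corr_spec("independent")
#' @seealso [empirical_correlation()], [synthetic_pathway31()]
#' @export
corr_spec <- function(kind = c("independent", "exchangeable", "empirical"),
                      rho = NULL, matrix = NULL, repair_tol = 1e-8) {
  kind <- match.arg(kind)
  if (kind == "independent") {
    rho <- 0
    matrix <- NULL
  } else if (kind == "exchangeable") {
    if (is.null(rho) || !is.numeric(rho) || length(rho) != 1 ||
        is.na(rho) || rho < 0 || rho >= 1) {
      abort("Exchangeable correlation requires a single `rho` in [0, 1).")
    }
    matrix <- NULL
  } else {
    if (is.null(matrix)) abort("Empirical correlation requires `matrix`.")
    matrix <- repair_correlation(as.matrix(matrix), repair_tol = repair_tol)
    rho <- NA_real_
  }
  structure(
    list(kind = kind, rho = rho, matrix = matrix,
         m = if (kind == "empirical") ncol(matrix) else NA_integer_),
    class = "gsa_corr_spec"
  )
}

#' @export
print.gsa_corr_spec <- function(x, ...) {
  switch(x$kind,
    independent = cat("<corr_spec> independent (identity)\n"),
    exchangeable = cat(sprintf("<corr_spec> exchangeable, rho = %g\n", x$rho)),
    empirical = cat(sprintf("<corr_spec> empirical, %d x %d matrix\n",
                            x$m, x$m))
  )
  invisible(x)
}

# Validate and repair a correlation matrix: symmetric, unit diagonal;
# eigenvalues below `repair_tol` are clipped and the matrix rescaled to
# unit diagonal (cov2cor). Errors name the offending eigenvalue if the
# repaired matrix is still not PSD.
repair_correlation <- function(mat, repair_tol = 1e-8) {
  if (nrow(mat) != ncol(mat)) abort("Correlation matrix must be square.")
  if (max(abs(mat - t(mat))) > 1e-8) {
    abort("Correlation matrix must be symmetric.")
  }
  mat <- (mat + t(mat)) / 2
  if (max(abs(diag(mat) - 1)) > 1e-6) {
    abort("Correlation matrix must have unit diagonal.")
  }
  diag(mat) <- 1
  dn <- dimnames(mat)
  ev <- eigen(mat, symmetric = TRUE)
  if (min(ev$values) < repair_tol) {
    vals <- pmax(ev$values, repair_tol)
    mat <- ev$vectors %*% (vals * t(ev$vectors))
    mat <- stats::cov2cor(mat)
    mat <- (mat + t(mat)) / 2
    dimnames(mat) <- dn
    ev2 <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev2) < -1e-10) {
      abort(sprintf(
        "Correlation matrix not positive semi-definite after repair (eigenvalue %.3e).",
        min(ev2)
      ))
    }
  }
  mat
}

# Full covariance/correlation matrix for a spec at set size m.
corr_sigma <- function(corr, m) {
  stopifnot(inherits(corr, "gsa_corr_spec"))
  switch(corr$kind,
    independent = diag(m),
    exchangeable = {
      S <- matrix(corr$rho, m, m)
      diag(S) <- 1
      S
    },
    empirical = {
      if (m != corr$m) {
        abort(sprintf(
          "Empirical correlation is %d x %d but m = %d was requested.",
          corr$m, corr$m, m
        ))
      }
      corr$matrix
    }
  )
}

# Upper-triangular factor R with Sigma = t(R) %*% R; Cholesky with an
# eigendecomposition fallback for semi-definite repaired matrices.
corr_factor <- function(corr, m) {
  if (corr$kind == "independent") return(diag(m))
  S <- corr_sigma(corr, m)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    ev <- eigen(S, symmetric = TRUE)
    if (min(ev$values) < -1e-8) {
      abort(sprintf("Covariance not PSD (eigenvalue %.3e).", min(ev$values)))
    }
    R <- sqrt(pmax(ev$values, 0)) * t(ev$vectors)
  }
  R
}

#' Estimate an empirical between-probe correlation structure
#'
#' Computes the pairwise Pearson correlation matrix of the probe columns of
#' an expression matrix and wraps it as an empirical [corr_spec()], so that
#' expression data can be simulated with a realistic, heterogeneous
#' correlation pattern. Eigenvalues below `repair_tol` are clipped and the
#' matrix rescaled to unit diagonal.
#'
#' @param X Samples x probes expression matrix or all-numeric data frame,
#'   at least 3 rows.
#' @param repair_tol Positive clipping tolerance for the PSD repair.
#' @return An empirical `gsa_corr_spec`.
#' @examples
#' X <- simulate_expression(500, corr_spec("exchangeable", rho = 0.3), m = 4,
#'                          seed = 1)
#' empirical_correlation(X)
#' @export
empirical_correlation <- function(X, repair_tol = 1e-8) {
  X <- as_expression_matrix(X)
  if (nrow(X) < 3) abort("Need at least 3 samples to estimate correlations.")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    ids <- colnames(X)[sds == 0]
    if (is.null(ids)) ids <- which(sds == 0)
    abort(paste0("Constant expression column(s): ",
                 paste(ids, collapse = ", ")))
  }
  cmat <- cor(X)
  if (any(abs(cmat[upper.tri(cmat)]) >= 1 - 1e-12)) {
    warn("Degenerate correlation: some probe pairs are perfectly correlated.")
  }
  corr_spec("empirical", matrix = cmat, repair_tol = repair_tol)
}

#' Synthetic 31-probe pathway correlation structure
#'
#' Loads the packaged 31 x 31 correlation matrix that stands in for the
#' correlation structure of a real drug-metabolism pathway measured on an
#' expression array. The matrix is synthetic: it was generated once, from a
#' fixed seed, under a block factor model (five co-regulated probe blocks
#' with within-block correlations between about 0.25 and 0.7, plus a weak
#' shared component), and is shipped as a plain-text fixture. It provides
#' the "empirical, heterogeneous correlation" scenario class for
#' simulations without requiring external data.
#'
#' @return An empirical `gsa_corr_spec` with `m = 31`.
#' @examples
#' corr <- synthetic_pathway31()
#' dim(corr$matrix)
#' @export
synthetic_pathway31 <- function() {
  path <- system.file("extdata", "synthetic_pathway31_corr.txt",
                      package = "gsaperm", mustWork = TRUE)
  mat <- as.matrix(utils::read.table(path, header = TRUE,
                                     check.names = FALSE))
  rownames(mat) <- colnames(mat)
  corr_spec("empirical", matrix = mat)
}
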