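#' Self-contained gene-set association test
#'
#' The central user-facing analysis: tests whether any probe in the gene
#' set is associated with the continuous phenotype, computing one or more
#' of the ten gene-set statistics together with permutation-based
#' empirical p-values from a single shared set of phenotype permutations
#' (so all methods see exactly the same permuted datasets). Asymptotic
#' p-values are reported where a method defines one (FM, SM, GMFE, PCA);
#' the permutation p-value is the recommended inference for correlated
#' probes. GMFE is reported as not applicable (`NA` p-values) when
#' `m > n - 2`.
#'
#' @param X Samples x probes expression matrix or all-numeric data frame.
#'   If both `X` rows and `y` are named, samples are aligned by name.
#' @param y Continuous phenotype vector (optionally named by sample).
#' @param methods Character vector from [gene_set_methods()]; default all
#'   ten.
#' @param B Number of phenotype permutations.
#' @param seed Optional integer seed for reproducible permutations.
#' @return A tibble of class `gsa_result`, one row per method, with
#'   columns `method`, `m`, `statistic`, `df`, `p_asymptotic`, `exceed`,
#'   `p_perm`, `B`, `applicable`; attributes record `n`, `m` and the seed.
#' @examples
#' X <- simulate_expression(40, corr_spec("exchangeable", 0.1), m = 8,
#'                          seed = 1)
#' y <- simulate_phenotype(X, beta_pattern(8, medium = 2), sigma = 3,
#'                         seed = 2)
#' gene_set_test(X, y, B = 199, seed = 3)
#' @export
gene_set_test <- function(X, y, methods = gene_set_methods(), B = 1000,
                          seed = NULL) {
  methods <- match_methods(methods)
  X <- as_expression_matrix(X)
  if (!is.null(rownames(X)) && !is.null(names(y))) {
    aligned <- align_samples(X, y)
    X <- aligned$X; y <- aligned$y
  }
  out <- perm_run(X, y, methods, B = B, seed = seed)
  structure(out, class = c("gsa_result", class(out)),
            n = nrow(X), m = ncol(X), seed = seed)
}

#' @export
print.gsa_result <- function(x, ...) {
  cat(sprintf("Self-contained gene-set test: n = %d samples, m = %d probes, B = %d permutations\n",
              attr(x, "n"), attr(x, "m"), x$B[1]))
  NextMethod()
}

#' @rdname gene_set_test
#' @param x,... A `gsa_result` and ignored further arguments.
#' @method tidy gsa_result
#' @export
tidy.gsa_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname gene_set_test
#' @method glance gsa_result
#' @export
glance.gsa_result <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"), m = attr(x, "m"), B = x$B[1],
    n_methods = nrow(x),
    min_p_perm = suppressWarnings(min(x$p_perm, na.rm = TRUE)),
    best_method = x$method[which.min(x$p_perm)]
  )
}

#' @rdname gene_set_test
#' @param object A `gsa_result`.
#' @param alpha Significance level drawn as a reference line.
#' @method autoplot gsa_result
#' @export
autoplot.gsa_result <- function(object, alpha = 0.05, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(.data$applicable) |>
    dplyr::mutate(method = factor(.data$method,
                                  levels = gene_set_methods()))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$method,
                                    y = -log10(.data$p_perm))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = expression(-log[10] ~ "empirical p-value"),
      title = "Self-contained gene-set tests",
      subtitle = sprintf("n = %d samples, m = %d probes, B = %d permutations",
                         attr(object, "n"), attr(object, "m"), object$B[1])
    ) +
    ggplot2::theme_minimal()
}
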