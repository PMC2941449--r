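#' Simulate a gene-set expression matrix
#'
#' Draws `n` independent samples from a multivariate normal distribution
#' with mean zero, unit variances, and between-probe correlation given by a
#' [corr_spec()]. This is the expression model used throughout the
#' simulation study: each row is one subject, each column one probe of the
#' gene set.
#'
#' @param n Number of samples (rows), at least 2.
#' @param corr A [corr_spec()]. For an empirical spec, `m` must equal the
#'   fixture's dimension.
#' @param m Number of probes (columns), at least 1.
#' @param seed Optional integer seed; given the same seed the result is
#'   bit-identical.
#' @return An `n` x `m` numeric matrix with probe column names.
#' @examples
#' X <- simulate_expression(5, corr_spec("independent"), m = 3, seed = 42)
#' dim(X)
#' @export
simulate_expression <- function(n, corr = corr_spec("independent"), m,
                                seed = NULL) {
  stopifnot(inherits(corr, "gsa_corr_spec"))
  if (n < 2) abort("`n` must be at least 2.")
  if (m < 1) abort("`m` must be at least 1.")
  local_seed_if(seed)
  R <- corr_factor(corr, m)
  X <- matrix(rnorm(n * m), n, m) %*% R
  colnames(X) <- if (corr$kind == "empirical" && !is.null(colnames(corr$matrix))) {
    colnames(corr$matrix)
  } else {
    sprintf("probe%03d", seq_len(m))
  }
  X
}

#' Simulate a continuous phenotype from expression
#'
#' Generates the phenotype conditional on expression under the linear model
#' `Y_i = x_i' beta + e_i` with `e_i ~ N(0, sigma^2)` independent across
#' subjects. With all effects zero the phenotype is pure noise,
#' independent of expression.
#'
#' @param X Samples x probes expression matrix.
#' @param beta Effect-size vector, one entry per probe column.
#' @param sigma Error standard deviation, > 0.
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector of length `nrow(X)`.
#' @examples
#' X <- simulate_expression(10, m = 2, seed = 1)
#' y <- simulate_phenotype(X, beta = c(2, 0), sigma = 1, seed = 2)
#' @export
simulate_phenotype <- function(X, beta, sigma = 1, seed = NULL) {
  X <- as_expression_matrix(X)
  if (length(beta) != ncol(X)) {
    abort(sprintf("`beta` has length %d but X has %d probe columns.",
                  length(beta), ncol(X)))
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  local_seed_if(seed)
  drop(X %*% beta) + rnorm(nrow(X), 0, sigma)
}

#' Theoretical phenotype variance explained by expression
#'
#' For the generative model `Y = X beta + e`, the proportion of phenotype
#' variance attributable to expression is
#' `R^2 = beta' Sigma beta / (beta' Sigma beta + sigma^2)`, where `Sigma`
#' is the (unit-variance) expression covariance implied by `corr`. Null
#' scenarios (all effects zero) have `R^2 = 0`.
#'
#' @param beta Effect-size vector.
#' @param corr A [corr_spec()] valid for `length(beta)` probes.
#' @param sigma Error standard deviation, > 0.
#' @return A proportion in `[0, 1)`.
#' @examples
#' theoretical_r2(c(1, 1), corr_spec("exchangeable", rho = 0.3), sigma = 3)
#' @export
theoretical_r2 <- function(beta, corr = corr_spec("independent"), sigma = 1) {
  stopifnot(inherits(corr, "gsa_corr_spec"), sigma > 0)
  if (all(beta == 0)) return(0)
  S <- corr_sigma(corr, length(beta))
  q <- drop(crossprod(beta, S %*% beta))
  q / (q + sigma^2)
}

#' Construct a simulation scenario
#'
#' A scenario is a complete generative specification for one simulation
#' cell: sample size, gene-set size, between-probe correlation, effect
#' sizes (conventionally 0/1/2/3 for no/small/medium/large), and error
#' standard deviation. A scenario is "null" when every effect is zero.
#'
#' @param n Sample size.
#' @param m Gene-set size; must match `length(beta)` and, for empirical
#'   correlation, the fixture dimension.
#' @param corr A [corr_spec()].
#' @param beta Effect-size vector of length `m`.
#' @param sigma Error standard deviation, > 0.
#' @param label Free-text label used in outputs and for seed derivation.
#' @return An object of class `gsa_scenario`.
#' @examples
#' scn <- scenario(100, 10, corr_spec("exchangeable", rho = 0.1),
#'                 beta = beta_pattern(10, small = 2), sigma = 3)
#' is_null_scenario(scn)
#' @export
scenario <- function(n, m, corr = corr_spec("independent"),
                     beta = rep(0, m), sigma = 1, label = NULL) {
  stopifnot(inherits(corr, "gsa_corr_spec"))
  n <- as.integer(n); m <- as.integer(m)
  if (length(beta) != m) {
    abort(sprintf("`beta` has length %d but m = %d.", length(beta), m))
  }
  if (corr$kind == "empirical" && m != corr$m) {
    abort(sprintf("Empirical correlation is for m = %d probes, not %d.",
                  corr$m, m))
  }
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (is.null(label)) {
    label <- sprintf(
      "n%d_m%d_%s%s_s%g_b%s", n, m, substr(corr$kind, 1, 3),
      if (corr$kind == "exchangeable") sprintf("%g", corr$rho) else "",
      sigma, paste(beta, collapse = "")
    )
    if (nchar(label) > 60) {
      label <- sprintf("n%d_m%d_%s_s%g_nb%d", n, m, substr(corr$kind, 1, 3),
                       sigma, sum(beta != 0))
    }
  }
  structure(
    list(n = n, m = m, corr = corr, beta = as.numeric(beta),
         sigma = as.numeric(sigma), label = label),
    class = "gsa_scenario"
  )
}

#' @export
print.gsa_scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario '%s'> n = %d, m = %d, corr = %s%s, sigma = %g, %d associated probe(s), R^2 = %.4f\n",
    x$label, x$n, x$m, x$corr$kind,
    if (x$corr$kind == "exchangeable") sprintf("(%g)", x$corr$rho) else "",
    x$sigma, sum(x$beta != 0), theoretical_r2(x$beta, x$corr, x$sigma)
  ))
  invisible(x)
}

#' Is a scenario null?
#'
#' @param scn A [scenario()].
#' @return `TRUE` when every effect size is zero.
#' @export
is_null_scenario <- function(scn) {
  stopifnot(inherits(scn, "gsa_scenario"))
  all(scn$beta == 0)
}

#' Build an effect-size vector from counts per effect grade
#'
#' Effect sizes take values 0, 1, 2 or 3 (no, small, medium, large). This
#' constructor places the requested number of probes at each non-zero
#' grade, followed by zeros, which is sufficient under independent or
#' exchangeable correlation where probe order is immaterial.
#'
#' @param m Gene-set size.
#' @param small,medium,large Counts of probes with effect 1, 2, 3.
#' @return Numeric vector of length `m`.
#' @examples
#' beta_pattern(10, small = 2, large = 1)
#' @export
beta_pattern <- function(m, small = 0, medium = 0, large = 0) {
  k <- small + medium + large
  if (k > m) abort("More associated probes than probes in the set.")
  c(rep(1, small), rep(2, medium), rep(3, large), rep(0, m - k))
}

#' Simulate one dataset under a scenario
#'
#' @param scn A [scenario()].
#' @param seed Optional integer seed (bit-identical reruns).
#' @return A list of class `gsa_dataset` with elements `X` (expression
#'   matrix), `y` (phenotype), `scenario`, and `seed`.
#' @examples
#' d <- simulate_dataset(scenario(20, 5), seed = 7)
#' dim(d$X); length(d$y)
#' @export
simulate_dataset <- function(scn, seed = NULL) {
  stopifnot(inherits(scn, "gsa_scenario"))
  local_seed_if(seed)
  X <- simulate_expression(scn$n, scn$corr, scn$m)
  y <- simulate_phenotype(X, scn$beta, scn$sigma)
  structure(list(X = X, y = y, scenario = scn, seed = seed),
            class = "gsa_dataset")
}

#' The full null simulation grid
#'
#' Enumerates all 114 null scenarios (every effect size zero) of the type-I
#' error study: the fixed-structure cross of sample size
#' `n in {20, 100, 500}`, set size `m in {10, 50, 100, 500}`, error SD
#' `sigma in {1, 3, 6}` and exchangeable correlation
#' `rho in {0, 0.1, 0.3}` (108 scenarios; `rho = 0` is recorded as
#' independent), plus 6 scenarios using the packaged 31-probe empirical
#' correlation structure (`n in {100, 500}` x `sigma in {1, 3, 6}`).
#'
#' @return A tibble with one row per scenario and columns `label`, `n`,
#'   `m`, `structure`, `rho`, `sigma`, `beta` (list-column), `r2`. Convert
#'   a row to an executable [scenario()] with [as_scenario()].
#' @examples
#' grid <- null_scenario_grid()
#' nrow(grid)
#' @export
null_scenario_grid <- function() {
  fixed <- tidyr::expand_grid(
    n = c(20L, 100L, 500L),
    m = c(10L, 50L, 100L, 500L),
    sigma = c(1, 3, 6),
    rho = c(0, 0.1, 0.3)
  ) |>
    dplyr::mutate(
      structure = ifelse(.data$rho == 0, "independent", "exchangeable")
    )
  emp <- tidyr::expand_grid(n = c(100L, 500L), sigma = c(1, 3, 6)) |>
    dplyr::mutate(m = 31L, rho = NA_real_, structure = "empirical")
  grid <- dplyr::bind_rows(fixed, emp) |>
    dplyr::mutate(
      beta = purrr::map(.data$m, ~ rep(0, .x)),
      r2 = 0,
      label = sprintf(
        "null_n%d_m%d_%s_s%g", .data$n, .data$m,
        ifelse(.data$structure == "exchangeable",
               sprintf("r%g", .data$rho), substr(.data$structure, 1, 3)),
        .data$sigma
      )
    ) |>
    dplyr::select("label", "n", "m", "structure", "rho", "sigma",
                  "beta", "r2")
  grid
}

#' Cross scenario factors into a grid
#'
#' General constructor for (non-null) scenario grids: crosses sample
#' sizes, set sizes, correlations, error SDs and effect-size patterns.
#' Patterns are given as counts of probes at each effect grade (see
#' [beta_pattern()]) so arbitrary compositions can be generated without
#' enumerating vectors by hand.
#'
#' @param n,m,sigma Numeric vectors of factor levels.
#' @param rho Exchangeable correlations; use 0 for independent probes.
#' @param patterns List of named vectors with any of `small`, `medium`,
#'   `large`, e.g. `list(c(small = 2), c(medium = 1, large = 1))`.
#' @return A scenario tibble in the same layout as [null_scenario_grid()].
#' @examples
#' scenario_grid(n = 100, m = 10, rho = c(0, 0.3), sigma = 3,
#'               patterns = list(c(small = 2)))
#' @export
scenario_grid <- function(n, m, rho = 0, sigma = 1,
                          patterns = list(c(small = 0))) {
  cells <- tidyr::expand_grid(
    n = as.integer(n), m = as.integer(m), rho = rho, sigma = sigma,
    pattern = seq_along(patterns)
  )
  rows <- purrr::pmap(cells, function(n, m, rho, sigma, pattern) {
    pt <- as.list(patterns[[pattern]])
    beta <- beta_pattern(m, small = pt$small %||% 0,
                         medium = pt$medium %||% 0,
                         large = pt$large %||% 0)
    structure_ <- if (rho == 0) "independent" else "exchangeable"
    corr <- if (rho == 0) corr_spec("independent") else
      corr_spec("exchangeable", rho = rho)
    r2 <- theoretical_r2(beta, corr, sigma)
    tibble::tibble(
      label = sprintf("n%d_m%d_r%g_s%g_p%d", n, m, rho, sigma, pattern),
      n = n, m = m, structure = structure_, rho = rho, sigma = sigma,
      beta = list(beta), r2 = r2
    )
  })
  dplyr::bind_rows(rows)
}

#' Convert a scenario-grid row to an executable scenario
#'
#' @param row One row of a scenario tibble (see [null_scenario_grid()]).
#' @param corr_matrix Optional correlation matrix for `structure ==
#'   "empirical"` rows; defaults to the packaged [synthetic_pathway31()]
#'   fixture.
#' @return A [scenario()].
#' @export
as_scenario <- function(row, corr_matrix = NULL) {
  if (inherits(row, "gsa_scenario")) return(row)
  row <- as.list(dplyr::slice(tibble::as_tibble(row), 1))
  corr <- switch(row$structure,
    independent = corr_spec("independent"),
    exchangeable = corr_spec("exchangeable", rho = row$rho),
    empirical = if (is.null(corr_matrix)) synthetic_pathway31() else
      corr_spec("empirical", matrix = corr_matrix),
    abort(sprintf("Unknown correlation structure '%s'.", row$structure))
  )
  beta <- row$beta
  if (is.list(beta)) beta <- beta[[1]]
  if (is.character(beta)) beta <- as.numeric(strsplit(beta, ",")[[1]])
  scenario(row$n, row$m, corr, beta = beta, sigma = row$sigma,
           label = row$label)
}

#' Write / read a scenario grid as tab-delimited text
#'
#' One row per scenario with the effect-size vector encoded as
#' comma-joined integers, so grids round-trip losslessly through plain
#' text.
#'
#' @param grid Scenario tibble (see [null_scenario_grid()]).
#' @param path File path.
#' @return `write_scenario_grid()` returns `path` invisibly;
#'   `read_scenario_grid()` returns the scenario tibble.
#' @export
write_scenario_grid <- function(grid, path) {
  out <- grid |>
    dplyr::mutate(beta = purrr::map_chr(.data$beta, paste, collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_scenario_grid
#' @export
read_scenario_grid <- function(path) {
  grid <- readr::read_tsv(
    path,
    col_types = readr::cols(
      label = readr::col_character(), n = readr::col_integer(),
      m = readr::col_integer(), structure = readr::col_character(),
      rho = readr::col_double(), sigma = readr::col_double(),
      beta = readr::col_character(), r2 = readr::col_double()
    )
  )
  grid |>
    dplyr::mutate(beta = purrr::map(.data$beta,
                                    ~ as.numeric(strsplit(.x, ",")[[1]])))
}
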