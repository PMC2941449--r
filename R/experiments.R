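#' Run one simulation scenario
#'
#' Estimates type I error (null scenario) or power (non-null scenario) for
#' a set of gene-set methods: for each of `D` replicate datasets an
#' expression matrix and phenotype are simulated under the scenario, every
#' method's empirical permutation p-value is computed from `B` shared
#' phenotype permutations, and the null hypothesis is rejected when
#' `p <= alpha`. Replicate substream seeds are derived deterministically
#' from `(seed, scenario label, replicate index)`, so results are
#' bit-identical regardless of the order in which scenarios are run.
#' Methods that are not applicable to a dataset (GMFE when `m > n - 2`)
#' are reported with `NA` rates rather than failing the run.
#'
#' @param scn A [scenario()] or one row of a scenario tibble.
#' @param D Number of replicate datasets.
#' @param B Permutations per dataset.
#' @param alpha Significance level for rejection (default 0.05).
#' @param methods Methods to evaluate (see [gene_set_methods()]).
#' @param seed Master integer seed.
#' @return A tibble with one row per method: `label`, `method`, `n`, `m`,
#'   `D`, `B`, `rejections`, `rate`, `mode`, `r2`, `applicable`.
#' @examples
#' scn <- scenario(50, 5, beta = beta_pattern(5, large = 2), sigma = 3)
#' run_scenario(scn, D = 20, B = 99, methods = c("FM", "KS"), seed = 1)
#' @export
run_scenario <- function(scn, D = 1000, B = 1000, alpha = 0.05,
                         methods = gene_set_methods(), seed = 1) {
  scn <- as_scenario(scn)
  methods <- match_methods(methods)
  stopifnot(D >= 1, B >= 1, alpha > 0, alpha < 1)
  key <- scenario_key(scn$label)
  R <- corr_factor(scn$corr, scn$m)
  rej <- stats::setNames(rep(0, length(methods)), methods)
  napp <- stats::setNames(rep(0L, length(methods)), methods)
  for (d in seq_len(D)) {
    sub <- derive_seed(seed, key, d)
    withr::with_seed(sub, {
      X <- matrix(rnorm(scn$n * scn$m), scn$n, scn$m) %*% R
      y <- drop(X %*% scn$beta) + rnorm(scn$n, 0, scn$sigma)
      res <- perm_run(X, y, methods, B = B)
    })
    ok <- res$applicable
    rej[res$method[ok]] <- rej[res$method[ok]] +
      (res$p_perm[ok] <= alpha)
    napp[res$method[!ok]] <- napp[res$method[!ok]] + 1L
  }
  nap <- unname(napp[methods])
  rj <- unname(rej[methods])
  tibble::tibble(
    label = scn$label, method = methods, n = scn$n, m = scn$m,
    D = as.integer(D), B = as.integer(B),
    rejections = ifelse(nap == D, NA_real_, rj),
    rate = ifelse(nap == D, NA_real_, rj / (D - nap)),
    mode = "permutation",
    r2 = theoretical_r2(scn$beta, scn$corr, scn$sigma),
    applicable = nap < D
  )
}

#' Type I error of Fisher's method with asymptotic p-values
#'
#' Evaluates Fisher's method using its chi-squared `2m` asymptotic
#' p-value, with no permutations. Under independent probes this p-value is
#' exact, but when expression values within the set are correlated the
#' independence assumption fails and the test's type I error inflates —
#' the phenomenon the permutation framework exists to avoid. This runner
#' quantifies that inflation.
#'
#' @inheritParams run_scenario
#' @return A one-row tibble in the same layout as [run_scenario()], with
#'   `mode = "asymptotic"` and `B = 0`.
#' @examples
#' scn <- as_scenario(null_scenario_grid()[1, ])
#' run_scenario_asymptotic_fm(scn, D = 100, seed = 1)
#' @export
run_scenario_asymptotic_fm <- function(scn, D = 1000, alpha = 0.05,
                                       seed = 1) {
  scn <- as_scenario(scn)
  stopifnot(D >= 1, alpha > 0, alpha < 1)
  key <- scenario_key(scn$label)
  R <- corr_factor(scn$corr, scn$m)
  rej <- 0
  for (d in seq_len(D)) {
    sub <- derive_seed(seed, key, d)
    withr::with_seed(sub, {
      X <- matrix(rnorm(scn$n * scn$m), scn$n, scn$m) %*% R
      y <- drop(X %*% scn$beta) + rnorm(scn$n, 0, scn$sigma)
    })
    p <- drop(probe_p_matrix(X, matrix(y, ncol = 1)))
    stat <- -2 * sum(log(p))
    pa <- pchisq(stat, 2 * scn$m, lower.tail = FALSE)
    rej <- rej + (pa <= alpha)
  }
  tibble::tibble(
    label = scn$label, method = "FM", n = scn$n, m = scn$m,
    D = as.integer(D), B = 0L, rejections = rej, rate = rej / D,
    mode = "asymptotic",
    r2 = theoretical_r2(scn$beta, scn$corr, scn$sigma),
    applicable = TRUE
  )
}

#' Run every scenario of a grid
#'
#' Convenience wrapper mapping [run_scenario()] (or the asymptotic FM
#' runner) over the rows of a scenario tibble and binding the outcome
#' rows. Each scenario derives its own substream seeds from its label, so
#' execution order does not affect results.
#'
#' @param grid Scenario tibble (e.g. from [null_scenario_grid()] or
#'   [scenario_grid()]).
#' @param mode `"permutation"` (all requested methods) or
#'   `"asymptotic_fm"` (Fisher's method with chi-squared p-values, no
#'   permutations).
#' @inheritParams run_scenario
#' @return Outcome tibble with one row per scenario x method.
#' @export
run_grid <- function(grid, D = 1000, B = 1000, alpha = 0.05,
                     methods = gene_set_methods(), seed = 1,
                     mode = c("permutation", "asymptotic_fm")) {
  mode <- match.arg(mode)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    scn <- as_scenario(grid[i, ])
    if (mode == "permutation") {
      run_scenario(scn, D = D, B = B, alpha = alpha, methods = methods,
                   seed = seed)
    } else {
      run_scenario_asymptotic_fm(scn, D = D, alpha = alpha, seed = seed)
    }
  })
}

#' Aggregate scenario outcomes into a method x sample-size table
#'
#' Averages rejection rates across scenarios within each (method, n) cell,
#' keeping null scenarios (mean type I error) separate from non-null
#' scenarios (mean power). Methods that were not applicable in a scenario
#' (GMFE in small samples) contribute only their applicable scenarios to
#' the mean; a cell with no applicable scenario is reported as missing
#' (`NaN` mean, 0 scenarios), never as zero.
#'
#' @param outcomes Outcome tibble from [run_scenario()] /
#'   [run_grid()].
#' @return A tibble of class `gsa_rate_table` with columns `method`, `n`,
#'   `null` (`TRUE` for type I error cells), `mean_rate`, `n_scenarios`.
#' @export
aggregate_rates <- function(outcomes) {
  out <- outcomes |>
    dplyr::mutate(null = .data$r2 == 0,
                  method = factor(.data$method,
                                  levels = gene_set_methods())) |>
    dplyr::group_by(.data$method, .data$n, .data$null) |>
    dplyr::summarise(
      mean_rate = mean(.data$rate[.data$applicable]),
      n_scenarios = sum(.data$applicable),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$method, .data$n)
  structure(out, class = c("gsa_rate_table", class(out)))
}

#' @rdname aggregate_rates
#' @param object A `gsa_rate_table`.
#' @param ... Ignored.
#' @method autoplot gsa_rate_table
#' @export
autoplot.gsa_rate_table <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(kind = ifelse(.data$null, "Type I error", "Power"))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$n),
                                    y = .data$mean_rate,
                                    fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "Sample size n", y = "Mean rejection rate",
                  fill = "Method") +
    ggplot2::theme_minimal()
}

#' Screen gene sets against a phenotype
#'
#' Applies the requested gene-set tests, with a common permutation scheme,
#' to each gene set of a collection (e.g. read from a GMT file): the
#' expression submatrix is extracted by probe identifier, members missing
#' from the expression matrix are dropped with a warning, and a set with
#' no matching probes yields a missing row rather than an error. P-values
#' are reported raw; Benjamini-Hochberg adjustment across sets (within
#' method) is available behind `adjust_bh`.
#'
#' @param X Samples x probes expression matrix with probe column names.
#' @param y Continuous phenotype aligned to rows of `X` (aligned by name
#'   when both are named).
#' @param sets A named list of probe-identifier vectors, or a tibble with
#'   columns `set` and `members` as produced by [read_gmt()].
#' @param B Permutations per gene set.
#' @param methods Methods to evaluate.
#' @param seed Master integer seed (per-set substreams derived from set
#'   names).
#' @param alpha Unused in screening; retained for symmetry.
#' @param adjust_bh Add a `p_adjusted` column (Benjamini-Hochberg across
#'   sets, within method)?
#' @return A long tibble with columns `set`, `m` (matched probes),
#'   `method`, `statistic`, `p_asymptotic`, `p_perm`, `B`, `applicable`.
#' @examples
#' X <- simulate_expression(40, m = 6, seed = 1)
#' y <- simulate_phenotype(X, beta_pattern(6, large = 2), seed = 2)
#' sets <- list(hit = colnames(X)[1:3], null = colnames(X)[4:6])
#' screen_gene_sets(X, y, sets, B = 99, methods = c("FM", "GMRE"), seed = 3)
#' @export
screen_gene_sets <- function(X, y, sets, B = 1000,
                             methods = c("KS", "FM", "SM", "TS", "MTS",
                                         "GMRE"),
                             seed = NULL, alpha = 0.05, adjust_bh = FALSE) {
  X <- as_expression_matrix(X)
  methods <- match_methods(methods)
  if (is.null(colnames(X))) abort("X must have probe column names.")
  if (!is.null(rownames(X)) && !is.null(names(y))) {
    aligned <- align_samples(X, y)
    X <- aligned$X; y <- aligned$y
  }
  if (tibble::is_tibble(sets) || is.data.frame(sets)) {
    members <- sets$members
    names(members) <- sets$set
    sets <- members
  }
  if (is.null(names(sets))) abort("Gene sets must be named.")
  rows <- purrr::imap(sets, function(ids, nm) {
    present <- intersect(ids, colnames(X))
    missing <- setdiff(ids, colnames(X))
    if (length(missing) > 0) {
      warn(sprintf("Gene set '%s': %d of %d probes absent from X.",
                   nm, length(missing), length(ids)))
    }
    if (length(present) == 0) {
      warn(sprintf("Gene set '%s' has no probes in X; row marked missing.",
                   nm))
      return(tibble::tibble(
        set = nm, m = 0L, method = methods, statistic = NA_real_,
        p_asymptotic = NA_real_, p_perm = NA_real_, B = as.integer(B),
        applicable = FALSE
      ))
    }
    sub <- if (is.null(seed)) NULL else derive_seed(seed, scenario_key(nm))
    res <- gene_set_test(X[, present, drop = FALSE], y, methods = methods,
                         B = B, seed = sub)
    tibble::tibble(
      set = nm, m = length(present), method = res$method,
      statistic = res$statistic, p_asymptotic = res$p_asymptotic,
      p_perm = res$p_perm, B = res$B, applicable = res$applicable
    )
  })
  out <- dplyr::bind_rows(rows)
  if (adjust_bh) {
    out <- out |>
      dplyr::group_by(.data$method) |>
      dplyr::mutate(p_adjusted = p.adjust(.data$p_perm, method = "BH")) |>
      dplyr::ungroup()
  }
  out
}
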