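# Shared statistic engine: computes each requested method's statistic for
# every phenotype column of Ymat (column 1 = observed, the rest permuted).
# All statistics are oriented so larger = more significant. Returns a
# list(stats = methods x ncol matrix, df = named list, applicable =
# named logical). Inapplicable methods (GMFE with m > n - 2) get NA rows.
compute_stat_matrix <- function(X, Ymat, methods) {
  n <- nrow(X); m <- ncol(X); nc <- ncol(Ymat)
  stats <- matrix(NA_real_, length(methods), nc,
                  dimnames = list(methods, NULL))
  df <- stats::setNames(vector("list", length(methods)), methods)
  applicable <- stats::setNames(rep(TRUE, length(methods)), methods)

  if (any(methods %in% .PVALUE_METHODS)) {
    P <- probe_p_matrix(X, Ymat)
    need_sorted <- any(methods %in% c("KS", "TS", "MTS"))
    Ps <- if (need_sorted) col_sort(P) else NULL
    if ("FM" %in% methods) {
      stats["FM", ] <- -2 * colSums(log(P))
      df[["FM"]] <- 2 * m
    }
    if ("SM" %in% methods) {
      stats["SM", ] <- colSums(qnorm(pmin(P, .P_CEIL),
                                     lower.tail = FALSE)) / sqrt(m)
    }
    if ("KS" %in% methods) {
      stats["KS", ] <- pmax(col_maxs(seq_len(m) / m - Ps), 0)
    }
    if ("TS" %in% methods) {
      stats["TS", ] <- colMeans(1 - Ps * ((m + 1) / seq_len(m)))
    }
    if ("MTS" %in% methods) {
      e <- rev(cumsum(1 / rev(seq_len(m))))
      stats["MTS", ] <- colMeans(-log(Ps) / e - 1)
    }
  }

  if ("GMRE" %in% methods) {
    stats["GMRE", ] <- gmre_stats(X, Ymat)
  }
  if ("GMFE" %in% methods) {
    if (m > n - 2) {
      applicable["GMFE"] <- FALSE
    } else {
      stats["GMFE", ] <- gmfe_stats(X, Ymat)
      df[["GMFE"]] <- c(m, n - m - 1)
    }
  }
  pca_methods <- intersect(methods, .PCA_METHODS)
  if (length(pca_methods) > 0) {
    sds <- apply(X, 2, sd)
    Xp <- if (any(sds == 0)) X[, sds > 0, drop = FALSE] else X
    if (ncol(Xp) == 0) abort("All probe columns have zero variance.")
    pca <- pca_basis(Xp)
    sel <- c(PCA1 = "first", `PCA1.5` = "top5", PCA80 = "var80")
    for (meth in pca_methods) {
      k <- pca_k(pca, sel[[meth]], n)
      stats[meth, ] <- pca_lrt_stats(pca, Ymat, k)
      df[[meth]] <- k
    }
  }
  list(stats = stats, df = df, applicable = applicable)
}

asymptotic_p <- function(method, stat, df, m, n) {
  if (is.na(stat)) return(NA_real_)
  switch(method,
    FM = pchisq(stat, 2 * m, lower.tail = FALSE),
    SM = pnorm(stat, lower.tail = FALSE),
    GMFE = pf(stat, df[1], df[2], lower.tail = FALSE),
    PCA1 = ,
    `PCA1.5` = ,
    PCA80 = pchisq(stat, df[1], lower.tail = FALSE),
    NA_real_
  )
}

# Core permutation run shared by the user-facing wrappers. Column 1 of the
# internal phenotype matrix is the observed y; columns 2..B+1 are uniform
# random permutations of it (sampled with replacement from the
# permutation group).
perm_run <- function(X, y, methods, B, seed = NULL) {
  X <- as_expression_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n != length(y)) abort("X and y dimensions disagree.")
  if (B < 1) abort("`B` must be at least 1.")
  if (sd(y) == 0) abort("Phenotype has zero variance.")
  local_seed_if(seed)
  Ymat <- cbind(y, vapply(seq_len(B), function(b) y[sample.int(n)],
                          numeric(n)))
  res <- compute_stat_matrix(X, Ymat, methods)
  obs <- res$stats[, 1]
  perms <- res$stats[, -1, drop = FALSE]
  exceed <- unname(rowSums(perms >= obs))   # ties count against rejection
  app <- unname(res$applicable[methods])
  p_asym <- vapply(methods, function(meth) {
    asymptotic_p(meth, obs[[meth]], res$df[[meth]] %||% NA_real_, m, n)
  }, numeric(1), USE.NAMES = FALSE)
  tibble::tibble(
    method = methods,
    m = m,
    statistic = unname(obs),
    df = vapply(methods, function(meth) (res$df[[meth]] %||% NA_real_)[1],
                numeric(1), USE.NAMES = FALSE),
    p_asymptotic = p_asym,
    exceed = ifelse(app, exceed, NA_real_),
    p_perm = ifelse(app, (exceed + 1) / (B + 1), NA_real_),
    B = as.integer(B),
    applicable = app
  )
}

#' Empirical permutation p-value for one gene-set statistic
#'
#' Estimates the significance of a gene-set statistic by permuting the
#' phenotype while holding the expression matrix fixed, which preserves
#' the between-probe correlation structure under the null of no
#' expression-phenotype association. For each of `B` uniform random
#' permutations of `y` the full statistic (including the per-probe
#' p-values for the combination methods) is recomputed; the empirical
#' p-value is `(count + 1) / (B + 1)`, where `count` is the number of
#' permutations whose statistic is as or more extreme (ties counting as
#' extreme) under the method's larger-is-more-significant orientation. The
#' `+1` smoothing keeps p-values strictly positive; the smallest
#' achievable value is `1 / (B + 1)`.
#'
#' @param X Samples x probes expression matrix or numeric data frame.
#' @param y Continuous phenotype aligned to rows of `X`.
#' @param method One of [gene_set_methods()].
#' @param B Number of permutations (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the exceed
#'   count exactly.
#' @return A one-row tibble with `method`, `m`, `statistic`, `df`,
#'   `p_asymptotic` (NA where undefined), `exceed`, `p_perm`, `B`,
#'   `applicable`.
#' @examples
#' X <- simulate_expression(30, m = 5, seed = 1)
#' y <- simulate_phenotype(X, beta_pattern(5, large = 1), seed = 2)
#' empirical_pvalue(X, y, "FM", B = 199, seed = 3)
#' @export
empirical_pvalue <- function(X, y, method, B = 1000, seed = NULL) {
  method <- match_methods(method)
  if (length(method) != 1) abort("Provide a single method.")
  if (method == "GMFE") {
    X <- as_expression_matrix(X)
    if (ncol(X) > nrow(X) - 2) {
      abort(sprintf(
        "GMFE is non-estimable: m = %d probes with only n = %d samples.",
        ncol(X), nrow(X)), class = "gsaperm_nonestimable")
    }
  }
  perm_run(X, y, method, B = B, seed = seed)
}

# All permutations of 1..n as an n! x n integer matrix.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- setdiff(seq_len(n), k)
    out[rows, 1] <- k
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates all `n!` permutations of the phenotype (identity included)
#' and returns the exact proportion whose statistic is as or more extreme
#' than the observed one. Only feasible for very small samples
#' (`n <= 8`); its role is as an exact reference for the Monte Carlo
#' estimate of [empirical_pvalue()], to which the latter converges as `B`
#' grows.
#'
#' @inheritParams empirical_pvalue
#' @return A one-row tibble like [empirical_pvalue()], with `B = n!` and
#'   `p_perm` the exact proportion (no smoothing; the identity permutation
#'   guarantees a positive numerator).
#' @examples
#' X <- simulate_expression(6, m = 3, seed = 1)
#' y <- simulate_phenotype(X, rep(0, 3), seed = 2)
#' exhaustive_pvalue(X, y, "TS")
#' @export
exhaustive_pvalue <- function(X, y, method) {
  method <- match_methods(method)
  if (length(method) != 1) abort("Provide a single method.")
  X <- as_expression_matrix(X)
  n <- nrow(X)
  if (n > 8) abort("Exhaustive enumeration is limited to n <= 8.")
  if (n != length(y)) abort("X and y dimensions disagree.")
  if (method == "GMFE" && ncol(X) > n - 2) {
    abort("GMFE is non-estimable for this X.", class = "gsaperm_nonestimable")
  }
  perms <- all_permutations(n)
  Ymat <- cbind(y, apply(perms, 1, function(idx) y[idx]))
  res <- compute_stat_matrix(X, Ymat, method)
  obs <- res$stats[1, 1]
  count <- sum(res$stats[1, -1] >= obs)
  tibble::tibble(
    method = method, m = ncol(X), statistic = obs,
    df = (res$df[[method]] %||% NA_real_)[1],
    p_asymptotic = asymptotic_p(method, obs, res$df[[method]] %||% NA_real_,
                                ncol(X), n),
    exceed = count, p_perm = count / nrow(perms),
    B = nrow(perms), applicable = TRUE
  )
}
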