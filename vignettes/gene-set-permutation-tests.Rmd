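---
title: "Self-contained gene-set tests with permutation significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-contained gene-set tests with permutation significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsaperm)
library(dplyr)
```

## The problem

A gene set (pathway) is a named collection of `m` expression probes. A
*self-contained* gene-set test asks whether expression of *any* gene in
the set is associated with a phenotype, using only the data for that set
— in contrast to competitive tests (GSEA-style), which compare the set
against its complement and therefore need genome-wide data. Self-contained
tests apply equally to genome-wide, candidate-gene and single-pathway
studies, and they admit subject-level permutation for exact significance.

gsaperm implements ten self-contained tests of the null hypothesis that no
probe in the set is associated with a continuous phenotype
(e.g. a drug-response IC50 measured on cell lines), together with
a common phenotype-permutation engine and a simulation module for studying
the tests' type I error and power.

## The ten tests

Throughout, `Y` is the length-`n` phenotype and `X` the `n x m` expression
submatrix for the set. Five tests combine per-probe association p-values;
five model the expression matrix jointly.

**Per-probe p-values.** Each probe is tested through the Pearson
correlation `r_i` between its expression and the phenotype:
`F_i = (n-2) r_i^2 / (1 - r_i^2)`, with the p-value `p_i` from the upper
tail of `F(1, n-2)` — identical to the slope t-test of the simple linear
regression. The probe-level test sits behind a single interface
(`probe_pvalues()`), so a different per-probe test could be substituted
for other phenotype types without touching the combination layer.

With ordered p-values `p_(1) <= ... <= p_(m)`:

* **KS** — one-sided Kolmogorov–Smirnov against Uniform(0,1):
  `d+ = max_i (i/m - p_(i))`, floored at 0. Sensitive to an excess of
  small p-values anywhere in the distribution.
* **FM** — Fisher's method: `-2 * sum(log p_i)`, chi-squared with `2m` df
  under independence. Asymmetric: dominated by the smallest p-values.
* **SM** — Stouffer's method: `sum(qnorm(1 - p_i)) / sqrt(m)`, standard
  normal under independence, tested one-sided against large values.
* **TS** — tail strength:
  `TS = (1/m) * sum_k [1 - p_(k) (m+1)/k]`; each ordered p-value is
  rescaled by its null expectation `k/(m+1)`, so `E(TS) = 0` under the
  null and `TS > 0` when ordered p-values run small.
* **MTS** — modified tail strength, the log-scale analogue: with
  `X_i = -log p_(i)` and `e_i = sum_{j=i}^m 1/j` (the expectation of the
  i-th largest of `m` standard exponentials),
  `MTS = (1/m) * sum_i (X_i / e_i - 1)`. Like TS it has null expectation
  0, but the log transform weights small p-values more heavily, in the
  spirit of FM.

* **GMFE** — global fixed-effects model: OLS of `y` on all `m` probes,
  overall `F(m, n-m-1)` test that every slope is zero. Only estimable
  when `m <= n - 2`; larger sets are reported *not applicable*.
* **GMRE** — global random-effects score test: probe effects are treated
  as random with common variance; the score test of "effect variance =
  0" reduces, for centered `X` and residuals `r = y - mean(y)`, to the
  quadratic form `Q = (r' X X' r) / (r' r)`.
* **PCA1 / PCA1.5 / PCA80** — likelihood-ratio chi-square (df = k) of
  `y ~ PC_1..PC_k` against the intercept-only model, with components from
  the correlation-matrix PCA of `X` and `k` = 1, `min(5, m, n-2)`, or the
  smallest `k` reaching 80% cumulative explained variance.

## Permutation significance

Correlation between probes (ubiquitous within pathways) breaks the
independence assumptions behind the FM/SM asymptotics and distorts the
null distribution of every combination statistic. The engine therefore
permutes the *phenotype* while holding the expression matrix fixed —
preserving the between-probe correlation exactly — and recomputes the full
statistic (probe p-values included) for each of `B` permutations. The
empirical p-value is `(count + 1) / (B + 1)`, where `count` is the number
of permutations whose statistic is at least the observed one.

Numerical conventions, all chosen for determinism:

* `+1` smoothing keeps p-values strictly positive (smallest value
  `1/(B+1)`); at `B = 1000` the difference from the raw proportion is
  below the resolution of any downstream simulation.
* Ties between a permuted and the observed statistic count *against*
  rejection (`>=` on the oriented statistic) — conservative.
* Permutations are sampled with replacement from the permutation group;
  distinctness is immaterial at `B << n!`. An exhaustive `n!` enumeration
  (`exhaustive_pvalue()`, `n <= 8`) serves as an exact reference, and the
  Monte Carlo estimate converges to it.
* Every statistic is oriented larger-is-more-significant, so one
  exceedance rule serves all ten methods, and any strictly monotone
  rescaling of a statistic yields the identical permutation p-value.
  (This is why GMRE's scale-free normalization by `r'r` is legitimate:
  it is a monotone rescaling of the unstandardized score statistic for
  any fixed dataset.)
* Probe p-values are floored at `1e-300` so `-log p` stays finite; exact
  `p = 1` is clipped just below 1 before the Stouffer transform.
* All methods share one set of permutations per dataset, which both
  saves a factor of ten in compute and removes between-method Monte Carlo
  noise from comparisons.
* KS significance uses the same phenotype-permutation scheme as the other
  methods rather than iid-Uniform Monte Carlo; both are calibrated for
  independent probes, but only permutation protects the level under
  correlated probes.

### The MTS variant choice

The "deviation from expectation" idea admits two readings: the literal
difference `(1/m) sum (X_i - e_i)` and the normalized ratio form above.
The literal form collapses: `sum X_i` is ordering-free, so the statistic
is an affine function of Fisher's statistic and its permutation p-value is
*identical* to FM's — it would not be a distinct test (the suite verifies
this identity). The ratio form mirrors TS's structure (TS rescales each
`p_(k)` by its null expectation) and yields a genuinely different test, so
it is the default; both variants are exposed in
`modified_tail_strength()` and neither is silently hidden.

## The simulation model

Expression for each subject is multivariate normal with mean zero and
unit variances; the between-probe correlation is one of

* **independent** — identity;
* **exchangeable** — common correlation `rho` (0.1 or 0.3 in the study
  grids);
* **empirical** — an arbitrary correlation matrix, normally estimated
  from real data with `empirical_correlation()` (eigenvalues below a
  tolerance are clipped and the matrix rescaled to unit diagonal).

Sampling is by Cholesky factorization of the correlation matrix, with an
eigendecomposition fallback for semi-definite repaired matrices. The
phenotype is linear in expression: `Y = X beta + e`, `e ~ N(0, sigma^2)`,
with effect sizes conventionally 0/1/2/3 (none/small/medium/large) and
`sigma` in {1, 3, 6}. The signal strength of a scenario is summarized by
`R^2 = beta' Sigma beta / (beta' Sigma beta + sigma^2)`
(`theoretical_r2()`).

`null_scenario_grid()` enumerates the full type-I-error design: the cross
of `n` in {20, 100, 500}, `m` in {10, 50, 100, 500}, `sigma` in {1, 3, 6}
and `rho` in {0, 0.1, 0.3} (108 cells), plus 6 cells (`n` in {100, 500} x
`sigma`) that use a packaged 31-probe empirical correlation structure —
114 null scenarios in all. Non-null grids are built with
`scenario_grid()`, which takes effect patterns as counts of probes at each
grade rather than hard-coded vectors, since published non-null designs
enumerate thousands of beta compositions.

```{r grid}
null_scenario_grid() |> count(structure, n)
```

### The synthetic 31-probe correlation fixture

The empirical-structure scenarios emulate simulating from the correlation
matrix of a real pharmacogenomic pathway (31 expression probes). No real
expression data ships with the package; `synthetic_pathway31()` loads a
**synthetic** stand-in generated once from a fixed seed under a block
factor model — five co-regulated blocks with within-block correlations
from about 0.25 to 0.7 plus a weak shared component, rescaled to a valid
correlation matrix. It reproduces the *qualitative* features that matter
for the tests (heterogeneous, block-structured positive correlation of
realistic magnitude); it does not reproduce any particular real pathway's
structure, negative correlations, or heavy-tailed expression
distributions, and conclusions drawn from it say nothing about any
specific dataset.

What the generator deliberately does not emulate: non-Gaussian expression
(real log-scale microarray intensities are heavier-tailed), probe-level
measurement artefacts, covariates, and non-linear expression-phenotype
relations. Passing simulation tests therefore demonstrates calibration
and relative power under the stated generative model, not performance
guarantees on arbitrary real data.

## Seeding and reproducibility

Scenario runners derive a substream seed for every (scenario label,
replicate) pair from the master seed by a small deterministic integer
mix, so results are bit-identical regardless of execution order or
parallel scheduling, and any single replicate can be regenerated in
isolation. User-facing simulators take explicit `seed` arguments; the
same seed gives bit-identical output.

## Reduced-scale reproduction

The published-scale experiment (114 null plus thousands of non-null
scenarios x 1000 datasets x 1000 permutations) is cluster-scale. The
package's own reproduction defaults, chosen so the whole suite runs in
minutes on one core while leaving the expected rates unchanged, are:

* calibration: the null grid stratified to all `n`, `m` in {10, 50}, all
  `rho`, `sigma = 1` (the permutation tests' level is invariant to
  `sigma`), at `D = 500` datasets x `B = 200` permutations;
* asymptotic-FM inflation: the full fixed grid per `rho` at reduced `D`
  (no permutations needed);
* power ordering: an `R^2` ladder at `n` in {20, 100, 500}, `m = 10`,
  `sigma = 6`, `D = 200`.

With these sizes the calibration check resolves the level to about
+/- 0.01 per method (pooled across 18 scenarios), and power comparisons to
about +/- 0.07 — adequate for the qualitative orderings, which are
large effects (FM's mean power exceeds KS's by 0.1-0.25 at n >= 100).

```{r calibration, eval = FALSE}
grid <- null_scenario_grid() |>
  filter(structure != "empirical", m %in% c(10, 50), sigma == 1)
out <- run_grid(grid, D = 500, B = 200, seed = 1)
aggregate_rates(out)
```

## Degenerate inputs and edge cases

* Constant probe or phenotype: probe test returns `r = 0, p = 1` with a
  warning; a zero-variance phenotype is an error (permutation would be
  meaningless).
* Zero-variance probe columns are dropped (with a warning) before PCA;
  GMRE handles them naturally (they contribute nothing to `XX'`).
* `p = 1` inputs: KS floors `d+` at 0; Stouffer clips below 1.
* Ties in p-values: stable sort, no randomization.
* GMFE with `m > n - 2` raises a classed non-estimability error;
  scenario runners catch it and report the method *not applicable*,
  aggregating its means over applicable scenarios only.
* PCA80's `k` is capped at `min(m, n - 2)` so the regression stays
  estimable even at `n = 20, m = 500`.

## A worked example

```{r example}
X <- simulate_expression(100, corr_spec("exchangeable", rho = 0.3),
                         m = 20, seed = 11)
y <- simulate_phenotype(X, beta_pattern(20, small = 2), sigma = 6,
                        seed = 12)
res <- gene_set_test(X, y, B = 999, seed = 13)
res
glance(res)
```

## Known limitations

* Continuous phenotypes only; binary/survival/multiclass extensions and
  covariate adjustment are out of scope.
* The per-probe test is the correlation F-test; a misspecified probe-level
  test invalidates every combination method built on it.
* Permutation p-values have resolution `1/(B+1)`; screening across many
  gene sets at stringent thresholds needs `B` raised accordingly.
* Asymptotic p-values for FM and SM assume independent probes and are
  reported for reference only; under correlated expression they are
  anticonservative (the inflation experiment quantifies by how much),
  and the permutation p-value should be used.
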