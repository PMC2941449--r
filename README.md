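# gsaperm

Self-contained gene-set association tests for continuous phenotypes, with
permutation-based significance.

## What it is for

Expression studies often ask a pathway-level question: is *any* gene in a
given set (a metabolic pathway, a curated gene set) associated with a
continuous trait such as a drug-response IC50, a metabolite level, or a
clinical measurement? A **self-contained** gene-set test answers exactly
that, using only the probes in the set — so it works for candidate-pathway
studies as well as genome-wide ones, unlike competitive (enrichment-style)
tests that need the genomic background.

gsaperm is for statisticians and genomics analysts who want those tests
with honest inference under correlated probes, plus the simulation
machinery to study their operating characteristics.

## The tests

Each probe `i` is first tested through the Pearson correlation `r_i`
between its expression and the phenotype:
`F_i = (n-2) r_i² / (1-r_i²) ~ F(1, n-2)`, giving p-values
`p_(1) ≤ … ≤ p_(m)`. Ten set-level tests are provided:

| Method | Statistic |
|---|---|
| KS | one-sided Kolmogorov–Smirnov `d⁺ = max_i (i/m − p_(i))` |
| FM | Fisher's method `−2 Σ log p_i` (χ²₂ₘ under independence) |
| SM | Stouffer's method `Σ Φ⁻¹(1−p_i) / √m` |
| TS | tail strength `(1/m) Σ_k [1 − p_(k)(m+1)/k]` |
| MTS | modified tail strength `(1/m) Σ_i (X_i/e_i − 1)`, `X_i = −log p_(i)`, `e_i = Σ_{j≥i} 1/j` |
| GMFE | global fixed-effects overall F-test (all m probes in one OLS; needs `m ≤ n−2`) |
| GMRE | global random-effects score statistic `Q = r'XX'r / r'r` |
| PCA1 / PCA1.5 / PCA80 | likelihood-ratio χ²ₖ test on the top 1 / top 5 / 80%-variance principal components |

Significance for every statistic comes from one shared engine that
permutes the phenotype while keeping the expression matrix — and hence
the between-probe correlation — fixed: the empirical p-value is
`(count + 1)/(B + 1)` over `B` permutations. Asymptotic p-values (FM, SM,
GMFE, PCA) are reported alongside, but the FM/SM asymptotics assume
independent probes and inflate badly under correlation; the package's
inflation experiment reproduces that failure mode.

## A worked example

```r
library(gsaperm)

# a 20-probe set with exchangeable correlation 0.3; two probes carry a
# small effect, against noise sd 6 (theoretical R² ≈ 0.067)
X <- simulate_expression(100, corr_spec("exchangeable", rho = 0.3),
                         m = 20, seed = 11)
y <- simulate_phenotype(X, beta_pattern(20, small = 2), sigma = 6,
                        seed = 12)
gene_set_test(X, y, B = 999, seed = 13)
```

```
Self-contained gene-set test: n = 100 samples, m = 20 probes, B = 999 permutations
# A tibble: 10 × 9
   method     m statistic    df p_asymptotic exceed p_perm     B applicable
 * <chr>  <int>     <dbl> <dbl>        <dbl>  <dbl>  <dbl> <int> <lgl>
 1 KS        20     0.457    NA  NA              10  0.011   999 TRUE
 2 FM        20    95.3      40   0.00000208      7  0.008   999 TRUE
 3 SM        20     4.23     NA   0.0000115       9  0.01    999 TRUE
 4 TS        20     0.595    NA  NA              10  0.011   999 TRUE
 5 MTS       20     1.34     NA  NA              18  0.019   999 TRUE
 6 GMFE      20     2.34     20   0.00415         0  0.001   999 TRUE
 7 GMRE      20    60.2      NA  NA               7  0.008   999 TRUE
 8 PCA1      20     6.72      1   0.00953         9  0.01    999 TRUE
 9 PCA1.5    20    12.8       5   0.0249         39  0.04    999 TRUE
10 PCA80     20    22.3      11   0.0219         29  0.03    999 TRUE
```

Every method detects this modest planted signal (`p_perm` is the
permutation p-value; `exceed` counts permutations beating the observed
statistic). Note FM's asymptotic p-value (2×10⁻⁶) is far smaller than its
honest permutation p-value (0.008) — the probes are correlated, so the
χ²₂ₘ reference is anticonservative; trust `p_perm`.

Real-data screening takes tab-delimited expression and phenotype files
plus GMT gene sets, via `read_expression()` / `read_phenotype()` /
`read_gmt()` / `screen_gene_sets()`, or the thin CLI at
`inst/scripts/gsaperm` (`run`, `simulate`, `reproduce-calibration`,
`reproduce-inflation` subcommands).

The simulation side exposes the generative model (multivariate-normal
expression with independent / exchangeable / empirical correlation;
phenotype linear in expression), the 114-scenario null grid
(`null_scenario_grid()`), scenario runners (`run_scenario()`,
`run_grid()`) and the type-I/power aggregation
(`aggregate_rates()`). See the vignette in `vignettes/` for the models,
conventions and design decisions.

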