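Package: gsaperm
Title: Self-Contained Gene-Set Association Tests for Continuous
    Phenotypes with Permutation Significance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-contained gene-set analysis of expression data against a
    continuous phenotype. Implements ten gene-set tests: five statistics
    that combine per-probe association p-values (one-sided
    Kolmogorov-Smirnov, Fisher's method, Stouffer's method, tail strength,
    and a log-scale modified tail strength) and five tests that model the
    expression data jointly (a global fixed-effects F-test, a global
    random-effects score test, and likelihood-ratio tests on the top 1,
    top 5, or 80%-variance principal components). Significance for every
    statistic is available from a common phenotype-permutation engine, so
    no test relies on independence of probes or on asymptotic null
    distributions. A simulation module generates multivariate-normal
    expression with independent, exchangeable, or empirical correlation
    structure and phenotypes linear in expression, and scenario runners
    estimate type I error and power at scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
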