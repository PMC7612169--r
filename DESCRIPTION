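Package: mvmrtools
Title: Pleiotropy-Robust Multivariable Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("MVMR", "Tools Developers", email = "mvmrtools@example.org",
           role = c("aut", "cre"))
Description: Estimators for multivariable Mendelian randomization (MVMR) from
    GWAS summary statistics that are robust to pleiotropic (invalid) genetic
    instruments: MM-estimation with Tukey's bisquare (MVMR-Robust), weighted
    least-absolute-deviations regression with a parametric bootstrap
    (MVMR-Median), and lasso-penalized per-variant intercepts with a
    heterogeneity-tuned post-lasso estimator (MVMR-Lasso), alongside the
    standard inverse-variance weighted, Egger and multivariable MR-PRESSO
    comparators.  Includes instrument-strength and multicollinearity
    diagnostics, a Monte-Carlo simulation harness for benchmarking the
    estimators under balanced and directional pleiotropy with and without the
    InSIDE assumption, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    jsonlite,
    data.table,
    yaml,
    optparse
Suggests:
    glmnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
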