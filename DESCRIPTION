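Package: hetmeta
Title: Between-Study Variance Estimation and Conclusion Sensitivity for
    Meta-Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fixed-effect and random-effects meta-analysis with a full family
    of between-study variance (tau-squared) estimators: DerSimonian-Laird and
    its two-step, bootstrapped and 0.01-floored variants, the Hedges variance
    component estimator and its two-step refinement, maximum and restricted
    maximum likelihood, the Sidik-Jonkman model error variance estimators, and
    Rukhin's Bayes-type estimators.  Includes inverse-variance,
    Mantel-Haenszel and Peto fixed-effect pooling with the Cochran Q, H2 and
    I2 heterogeneity statistics, profile-likelihood confidence intervals, a
    simulation framework for assessing estimator performance (bias, rate of
    zero heterogeneity estimates, coverage, error-interval calibration), and
    machinery to cross-tabulate the sensitivity of statistical conclusions to
    the choice of heterogeneity method over a corpus of meta-analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
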