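Package: rctbalance
Title: Quantitative Assessment of Baseline Imbalances in Portfolios of
    Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Meta-epidemiological diagnostics for the integrity of
    randomization across a portfolio of two-arm randomized trials reported
    at the summary level. Computes per-trial baseline differences at
    reported precision with exact one-sided sign tests on their direction,
    fixed-effect inverse-variance pooling of baseline mean and risk
    differences with Q, I-squared and test-based I-squared confidence
    intervals, standard-deviation imbalance diagnostics (pooled SDs,
    t-tests on SD collections, per-trial variance-ratio tests and their
    p-value distribution), and univariate random-effects (DerSimonian-Laird)
    meta-regression of baseline imbalances against trial outcome effects.
    Includes a seeded generator of synthetic trial portfolios with known
    truth - intact or systematically broken randomization and
    covariate-linked outcomes - so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
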