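Package: sitesig
Title: Site-Specific Prognostic Biomarker Discovery with Genetic-Algorithm
    Feature Selection and Survival Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery and evaluation of site-specific transcriptomic
    prognostic signatures from expression and censored survival data.
    Implements a four-criterion differential-expression filter (call rate,
    fold change, t test, univariate Cox), genetic-algorithm wrapper feature
    selection with support-vector-machine and Cox fitness functions,
    frequency-ranking consensus with forward selection, Cox risk scores with
    median-split survival analysis, p-value-driven stepwise Cox models,
    time-dependent ROC curves for censored outcomes, Harrell's concordance
    index with bootstrap optimism correction, nomograms with calibration and
    decision-curve analysis, and a seeded synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    e1071,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
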