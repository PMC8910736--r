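Package: carbonylr
Title: Carbonyl Metabolome Profiling with Derivative-Stability Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untargeted profiling of reactive carbonyl compounds
    (RCCs) measured by LC-MS as 7-(diethylamino)coumarin-3-carbohydrazide
    (CHH) hydrazone derivatives. Provides hydrazone formula arithmetic,
    monoisotopic mass and ppm-error calculation, elemental-composition
    candidate search, MS/MS diagnostic-fragment and neutral-loss annotation,
    a quality-control-based correction for derivative degradation and signal
    drift (MinMax scaling, time-series k-means with Euclidean, dynamic time
    warping and DTW barycenter averaging metrics, per-analyte kinetics
    regression with correction coefficients), pooled-variance differential
    abundance testing with hierarchical clustering of significant features,
    and a synthetic batch generator with planted kinetics classes and fold
    changes for end-to-end validation.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
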