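Package: technome
Title: Internal Calibration of Quantitative Imaging Features via Qualified Control-Region Surrogates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Qualifies control-region (CR) surrogate features as proxies of
    technical variation in quantitative imaging cohorts by four criteria
    (in-vivo association, in-silico noise co-response, in-vitro phantom
    co-variation, orthogonality to the biological label), combines them into a
    weighted qualification score tuned by Gaussian-process Bayesian
    optimisation of a prediction-plus-calibration loss, and uses the qualified
    surrogates either to explicitly stabilise features (covariate-adjustment
    regression) or to implicitly calibrate a classifier. Includes RAVEL-like
    SVD calibration, naive GLM (mRMR + AIC) and random-forest baselines, a
    grouped cross-validation / small-sample validation harness, weight-space
    sweeps, and a synthetic-cohort generator with a closed-form Bayes-AUC
    oracle for ground-truth testing.
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
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
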