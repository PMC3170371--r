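Package: sgofplus
Title: Sequential Goodness-of-Fit Multiple Testing with q-Value Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple hypothesis testing by the sequential goodness-of-fit
    (SGoF) metatest and its automatic-threshold extension SGoF+, which selects
    the rejection region at the point of maximum distance between the empirical
    p-value distribution and the uniform (a Youden-index rule on the p-value
    ECDF) and protects weak family-wise error control with a one-sided
    Kolmogorov-Smirnov guard. Includes four estimators of the proportion of
    true null hypotheses (spline smoothing, bootstrap lambda selection, the
    location-based estimator, and standard-deviation-proportional bounding),
    robust and standard positive false discovery rate (pFDR) and q-value
    estimation, Benjamini-Hochberg and Holm baselines, a one-sample t-test
    simulation engine for power and pFDR studies, and evaluation metrics
    (power, FPR, pFDR, FWER, power/pFDR ratio).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
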