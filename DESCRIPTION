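Package: insulindex
Title: Surrogate Insulin Sensitivity Indices and Their Rank Equivalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for the common surrogate measures of insulin
    sensitivity (HOMA-IR, QUICKI, FIRI, Matsuda, Stumvoll, revised QUICKI and
    the fasting ratios), exact closed-form transformations between HOMA-IR,
    QUICKI and FIRI, and a statistical toolkit (Pearson and Spearman
    correlation, Spearman-to-Pearson conversion, ROC curves with trapezoidal
    AUC, Mann-Whitney and Welch tests) for method-comparison studies against
    a hyperinsulinemic euglycemic clamp reference. A seeded simulation
    pipeline generates correlated lognormal cohorts calibrated to a target
    Pearson correlation between QUICKI and the clamp measure, and
    demonstrates that the three fasting indices are rank-equivalent: equal
    Spearman correlations, identical ROC curves and AUCs, and identical
    nonparametric test results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    pROC,
    jsonlite
Config/testthat/edition: 3
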