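Package: cindexr
Title: Composite Inflammatory Biomarker Index for Infection Prediction at Fever Onset
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating a mean-normalized composite index (CIndex) of
    three serum inflammation biomarkers (procalcitonin, C-reactive protein and
    interleukin-6) as a predictor of microbiologically documented infection at
    the onset of fever in haematological patients. Provides a fitting function
    returning a classed model object with the usual methods, per-group summary
    statistics, exact and approximate Wilcoxon-Mann-Whitney rank tests,
    empirical ROC curves with Youden-optimal cut-offs, a lognormal
    moment/quantile-matched synthetic cohort generator for a two-group febrile
    cohort, and CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
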