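Package: landboost
Title: Dynamic Landmark-Boosted Risk Prediction from Longitudinal Clinical Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rolling one-year risk prediction from irregular longitudinal
    clinical event data using landmark analysis with gradient boosted trees.
    At each yearly landmark time a boosted-tree model is re-ensembled on
    updated predictors, carrying the previous landmark's predicted risk
    forward as a baseline log-odds offset (Landmark-Boosting).  The package
    ships a compact Newton-boosted tree learner with adaptive missing-value
    splits and early stopping, three comparator temporal representations
    (latest-value, stacked-window, discrete-time survival), electronic
    health record phenotyping for diabetes onset and diabetic kidney
    disease, an evaluation suite (AUROC, AUPRC, top-fraction threshold
    metrics, bootstrap intervals, binned observed-to-expected calibration),
    and a synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    xgboost,
    knitr
Config/testthat/edition: 3
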