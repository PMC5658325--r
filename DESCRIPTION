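Package: lfaquant
Title: Quantification and Calibration of Competitive Lateral-Flow Assay Strips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Image-based quantification chain for competitive lateral-flow
    immunoassays read by a strip imager, developed around a 25-hydroxyvitamin
    D3 assay. Provides a synthetic strip-image simulator with known ground
    truth, intensity-profile extraction with prominence-based test/control
    line detection and baseline-relative test/control (T/C) ratio computation,
    linear and four-parameter-logistic calibration (fitting and inverse
    prediction with censoring), vitamin-D status classification under named
    guideline thresholds, and diagnostic-performance statistics (empirical
    ROC, DeLong AUC with variance and confidence interval, stratified
    bootstrap AUC, diagnostic accuracy, RMSE and replicate coefficient of
    variation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
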