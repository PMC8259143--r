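Package: renalroi
Title: ROI-Based Quantitation of Four-Phase Renal CT for Fat-Poor
    Angiomyolipoma versus Small Clear Cell RCC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of four-phase contrast-enhanced renal CT
    (pre-contrast, corticomedullary, nephrographic and excretory phases) for
    distinguishing fat-poor renal angiomyolipoma from small clear cell renal
    cell carcinoma.  Implements three region-of-interest (ROI) measurement
    protocols (a small ROI over the most-enhancing patch, a smaller ROI
    restricted to it, and a whole-tumor ROI), the derived enhancement and
    heterogeneity parameters (net enhancement value, relative enhancement
    ratio, heterogeneous degree, standardized heterogeneous ratio), the
    accompanying statistical comparison suite (normality-dispatched two-group
    tests, chi-square, inter-observer ICC, nonparametric ROC/AUC), per-phase
    logistic prediction models with published fixed coefficients as well as
    refitting and backward variable screening, and a synthetic phantom and
    cohort generator so the whole pipeline can be exercised without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nortest,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    lme4,
    withr
Config/testthat/edition: 3
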