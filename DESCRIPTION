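Package: mammocad
Title: Hybrid CAD Pipeline for Breast Lesion Classification from Mammogram ROIs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline for classifying breast lesion
    regions of interest (ROIs) from grayscale mammograms. Implements pseudo-color
    channel synthesis (original, CLAHE-equalized, and percentile-stretched
    channels), frozen deep-feature extraction behind a verifiable backbone
    contract with a deterministic offline fallback extractor, the LR-PCA
    feature-reduction algorithm (covariance PCA with eigenvalue-magnitude
    ranking, pooled or class-wise, followed by Wald-significance selection of
    principal components via binomial logistic regression), multicollinearity
    diagnostics, and a classical classifier bank evaluated with the full
    confusion-matrix metric suite (accuracy, sensitivity, specificity,
    precision, FNR, FPR, AUC, MCC, F1). Seeded synthetic ROI and feature-table
    generators make every stage testable without any dataset download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    MASS,
    rpart,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
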