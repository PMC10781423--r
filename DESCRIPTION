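Package: emtseek
Title: Detection of Disseminating EMT Cancer Stem Cells in Multiplexed
    Immunofluorescence Fields and Image-Based Metastasis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies triple-positive (EpCAM+ Vimentin+ CD24+)
    disseminating tumour cells in four-colour immunofluorescence fields of
    tumour-stroma boundaries. Detects nucleated cells from the DAPI channel,
    separates the tumour body from the adjacent stroma with a marker
    "dense cloud" mask, extracts per-cell grey levels, calls marker
    positivity against 1.5x-median negative-control thresholds, applies
    field-level quality control, compares metastatic and non-metastatic
    cohorts, and trains field-level classifiers (including an epoch-traced
    feed-forward neural network) to predict metastatic status with
    cross-validated F1, ROC/AUC and majority-vote slide calls. Includes a
    seeded synthetic-field and cohort generator with full ground truth, and
    threshold-based marker co-expression analysis for single-cell RNA-seq
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    e1071,
    rpart,
    class,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
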