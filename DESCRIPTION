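Package: pulmoseg
Title: Lung Field Segmentation in Axial CT by Parzen-Window Boundary Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase lung-field segmentation for axial chest CT slices. Phase
    one is a slice-level lung-presence gate trained with z-score normalisation,
    random-search 5-fold cross-validation and F1-based model selection. Phase
    two refines a coarse lung mask (for example a detector's output) by
    shrinking it into a seed, estimating per-pixel lung membership with a
    Parzen-window kernel density estimate, and growing or contracting the
    region boundary until it stabilises on the lung wall. Includes the full
    pixel-level evaluation suite (accuracy, sensitivity, Matthews correlation,
    Jaccard, Dice, Hausdorff distance, Friedman/Nemenyi comparison), a seeded
    synthetic thoracic-phantom generator with exact ground truth, and readers
    for single-frame DICOM and grayscale PNG/TIFF slices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    class,
    e1071,
    jsonlite,
    nnet,
    png,
    randomForest,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
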