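Package: gazecft
Title: Gaze-Weighted Tensor Fusion for Emotional Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies images into emotional categories from eye-gaze
    recordings. Builds a gaze-weighted multi-frame image representation
    from fixation maps, extracts per-frame features from multiple
    backbones, fuses them into a third-order feature tensor, applies
    General Tensor Discriminant Analysis (GTDA) for supervised
    multilinear dimensionality reduction, and classifies with
    L1-regularized logistic tensor regression. Ships a synthetic
    scene/scanpath generator so the full pipeline is exercisable
    without human-subject data, plus evaluation utilities (precision,
    recall, F1, Welch's t-test) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
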