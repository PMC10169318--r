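Package: granulenet
Title: Deep Residual Feature Extraction and Model Stacking for
    Electron-Dense Granule Detection in Renal Biopsy Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Binary classification of transmission electron micrographs of
    renal biopsies by presence of electron-dense immune deposits. Implements
    a ResNet-50-style residual feature extractor with a fine/coarse skip
    concatenation (stage-2 and stage-5 feature maps), a support vector
    machine head on the concatenated deep features, a conventional softmax
    baseline, and an artificial-neural-network stacking combiner that fuses
    the two base models. Ships a seeded synthetic micrograph generator that
    emulates granule-bearing images, a full confusion-matrix/ROC evaluation
    suite, and an end-to-end pipeline with cohort splitting and report
    generation. Network forward passes are computed with im2col patch
    extraction and BLAS matrix products; no deep-learning framework is
    required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
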