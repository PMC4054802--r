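Package: complexion
Title: Qualitative and Quantitative Facial Complexion Analysis in CIELAB Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for computerized facial inspection as used in
    Traditional Chinese Medicine complexion diagnosis. Detects facial skin in
    log-opponent chromaticity space, constructs four facial chromaticity bases
    (normal, cyan, red, yellow) by two-level fuzzy c-means clustering,
    represents each face as a luminance-binned complexion histogram,
    recognizes six facial-color classes with a one-against-one radial-kernel
    support vector machine under leave-one-out cross-validation, and estimates
    per-subject color and gloss degrees with unsupervised ranking functions.
    Ships a synthetic-face generator with known ground truth so that every
    stage of the pipeline can be validated without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    mclust,
    EBImage,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
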