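Package: afpheno
Title: Autofluorescence Stress Phenotyping from Top-View Plant Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for pixel-level drought-stress phenotyping from top-view plant
    autofluorescence images. Segments plant regions by colour thresholding with
    age-dependent channel selection, builds pixel-level ground truth from annotated
    leaf patches, trains and compares six classifier families to map plant pixels to
    stressed/non-stressed, and computes two stress phenotypes per plant and day:
    average percentage stress and its trailing moving average. Includes a seeded
    synthetic-image generator emulating multi-genotype progressive-drought
    experiments with per-pixel ground truth, genotype comparison via Welch t-tests,
    ggplot2 visualisations, and a thin command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    withr,
    zoo,
    png,
    tiff,
    EBImage,
    randomForest,
    nnet,
    e1071,
    rpart,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
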