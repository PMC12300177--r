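Package: cowpose
Title: Cattle Head and Ear 3D Pose Annotation and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for annotating and evaluating the 3D orientation (yaw,
    pitch, roll) of cattle heads and ears in images. Implements the classic
    POSIT (pose from orthography and scaling, with iterations) solver over
    bespoke 21-point cattle-head and 13-point left-ear landmark schemes,
    object-detection evaluation (IoU, precision/recall, average precision)
    and pose mean-absolute-error metrics, the pixelwise feature scoring
    functions used by fine-grained pose regressors (uniform, variance,
    learnable 1x1 convolution), and a deterministic synthetic-scene
    generator for end-to-end validation. Readers and writers for VGG Image
    Annotator (VIA) project JSON, correspondence CSV, pose records and
    dataset manifests are included, plus a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
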