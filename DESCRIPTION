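Package: rfctsr
Title: Low-Dose CT Super-Resolution with Regression Random Forests and
    Coupled Dictionaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based restoration of low-dose (quarter-dose) computed
    tomography images toward full-dose quality. A regression random forest
    with closed-form ridge leaf models learns the mapping from low-dose
    patch features to high-dose patch detail; a coupled dictionary pair
    sharing one sparse code provides an l1 sparse-consistency reconstruction
    stage; an iterative refinement loop re-applies the trained mapping.
    Includes a synthetic ellipse-phantom generator with image-domain
    Gaussian and projection-domain Poisson dose degradation so the whole
    pipeline is trainable and testable without clinical data, plus PSNR and
    global SSIM image-quality metrics and a bicubic-interpolation baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
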