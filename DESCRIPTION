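Package: dermpipe
Title: Dermoscopy Image Classification Pipeline with Metadata Fusion and
    Ensemble Subset Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested implementation of a winning ISIC 2019
    skin-lesion classification pipeline: automatic field-of-view cropping of
    dermoscopic images via moment-ellipse fitting, Shades-of-Gray color
    constancy, ISIC-style patient metadata encoding with a missing-value
    sentinel, class-balanced two-stage training of a two-branch
    (image + metadata) classifier with lesion-grouped cross-validation,
    deterministic multi-crop test-time augmentation, and exhaustive
    ensemble subset selection driven by mean sensitivity.  Ships a synthetic
    dermoscopy fixture generator and a tiny convolutional backbone so that
    every stage runs on a single CPU without external datasets or
    pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    pROC,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
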