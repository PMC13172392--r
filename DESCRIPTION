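Package: tissuedetect
Title: Tissue Detection Comparison for Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares classical Otsu-threshold tissue segmentation against a
    trainable encoder-decoder segmenter on whole-slide images, and measures
    the downstream effect of the segmentation choice on slide-level prostate
    cancer (ISUP) grading. Provides a synthetic pyramidal-slide generator
    with exact ground-truth tissue and lesion masks, the tiling and
    overlap-discard inference conventions used by patch-based pipelines,
    and the full paired statistical evaluation: pixel-wise sensitivity and
    precision, exact binomial (Clopper-Pearson) confidence intervals,
    McNemar's test on paired detection failures, quadratic weighted kappa
    with bootstrap confidence intervals, and discordance accounting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
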