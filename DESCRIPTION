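Package: wsicyto
Title: Whole-Slide Multiplexed Immunohistochemistry Tissue Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A whole-slide image analysis pipeline for multiplexed
    immunohistochemistry (mIHC) combining fluorescence and chromogenic
    detection. Registers brightfield and fluorescence whole-slide images by
    blob-feature matching, separates chromogens by optical-density colour
    de-convolution, segments epithelial glands and cell nuclei with Otsu
    thresholding and watershed declumping, quantifies marker expression per
    cell, classifies cells into immune (T regulatory/helper/effector) and
    epithelial (basal, benign luminal, cancer) classes, and computes
    tissue-cytometry summaries and the associated statistics. A built-in
    synthetic-slide generator with full ground truth supports end-to-end
    validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
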