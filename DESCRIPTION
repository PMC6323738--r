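Package: fibercsa
Title: Semi-Automated Myofiber Cross-Sectional Area Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures myofiber cross-sectional area (CSA) on laminin-stained
    muscle section images through a semi-automated pipeline: Huang
    minimum-fuzziness thresholding, binary morphology (opening, hole filling),
    connected-component particle analysis with calibrated size and circularity
    filters, whole-section tiling with seam-aware merging, and a programmatic
    manual-correction layer (delete false fibers, add hand-drawn ones) with
    ImageJ ROI interoperability. Ships a synthetic muscle-section generator
    with exact per-fiber ground truth emulating uninjured, regenerating and
    fibrotic histology, and an evaluation layer (truth matching by
    intersection-over-union, CSA distributions, identity-line correlation,
    correction burden, whole-section versus subset bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
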