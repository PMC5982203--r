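Package: psep
Title: Locating Cereal Plant Stem Emerging Points in Field Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating plant stem emerging points (PSEPs) of drilled
    cereals in top-view field images. Point annotations are rasterized into
    disk label masks with non-punishing halos; penalty regions are derived
    from the false positives of a baseline model and folded into a
    penalty-weighted cross-entropy loss used to train a fully-convolutional
    two-class segmentation network with skip fusion. Detections are extracted
    from thresholded softmax maps and scored by one-to-one point matching
    (precision, recall, F1), with model selection over a penalty-weight by
    softmax-threshold grid. Survey utilities classify per-image counts into
    density ranges, draw stratified evaluation samples, regress predicted on
    annotated counts, and render geo-referenced field maps. A synthetic
    field-scene generator with emergence-point ground truth and
    leaf-tip/residue distractors makes the whole pipeline testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
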