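Package: mitomorph
Title: Mitochondrial Ultrastructure Morphometry and Instance-Segmentation
    Evaluation for Transmission Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of mitochondria in transmission
    electron microscopy (TEM) sections of glioma tissue. Reads instance
    annotations as label images or COCO-style polygon JSON, computes
    per-mitochondrion shape indices (area, perimeter, circularity) and
    per-cell aggregates (density, area ratio), quantifies respiratory-cristae
    occupancy, assigns a three-type cristae-health classification and the
    low-grade/high-grade (LGG/HGG) glioma grouping, and evaluates predicted
    instance segmentations against ground truth with IoU-thresholded
    one-to-one matching, macro-averaged Precision/Recall/F1 and signed
    perimeter/area error rates. A synthetic-data generator produces
    grade-profiled annotated images and controllably perturbed prediction
    sets so the whole pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
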