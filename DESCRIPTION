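Package: polyqc
Title: Quality Control for COCO Polygon Instance-Segmentation Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validates polygon geometry in COCO instance-segmentation
    datasets, rasterizes annotations to native-resolution binary masks,
    suppresses noise-like instances with a pixel-area threshold, renders
    semi-transparent overlay visualizations for manual review, exports
    cleaned annotations to COCO and YOLO segmentation formats, and
    compares two segmentations via frame-level Dice similarity and the
    paired Wilcoxon signed-rank test. Includes a seeded synthetic-dataset
    generator with a ground-truth defect manifest so every pipeline stage
    can be tested without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    png,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
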