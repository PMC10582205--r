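Package: embryovision
Title: Organizing Grouped-Embryo Microscopy Videos into Per-Embryo Image Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts microscopic observation videos of group-cultured IVF
    embryos into an organized library of clear per-embryo image crops.
    Provides frame-stream decoding with temporal downsampling, a pluggable
    embryo detection contract (a weight-free classical blob detector and a
    reader for normalized YOLO-format detection files), detection-driven
    partitioning of a video into growth-medium segments, left/right embryo
    identity assignment, a Day/Patient/Medium/Embryo folder writer,
    variance-of-Laplacian blur classification with day-specific bands, and
    object-detection evaluation (IoU matching, precision/recall, average
    precision, mAP at 0.5 and 0.5:0.95). A seeded synthetic microscopy video
    generator with per-frame ground-truth manifests makes every stage
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
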