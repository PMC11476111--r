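Package: wildetect
Title: Knowledge-Guided Multimodal Wildlife Detection at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A fully testable, CPU-scale implementation of a multimodal
    (vision plus text) two-stage wildlife detector for camera-trap style
    imagery. Provides a reproducible synthetic scene generator with
    COCO-style annotations; a species knowledge base of templated textual
    descriptors with composed description-plus-label knowledge vectors;
    region-text contrastive alignment with teacher-student distillation; a
    cross-attention concept enhancement block with residual feedforward
    fusion; continuous feature scaling on the unit hypersphere with a
    learnable scale factor; region-proposal and ROI-head detection with
    cross-entropy and smooth-L1 losses; and a detection metric suite
    (AP/mAP over IoU 0.5-0.95, size-stratified AP, detection and miss
    rates, confusion matrices, and empty-shot absence testing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
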