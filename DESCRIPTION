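Package: cbdetect
Title: Centroblast Detection, Evaluation and Follicular-Lymphoma Grading Toolkit
Version: 0.1.0
Authors@R:
    person("cbdetect", "maintainers", email = "cbdetect@example.org",
           role = c("aut", "cre"))
Description: Detector-agnostic toolkit for counting centroblasts in H&E-stained
    histology patches and grading follicular lymphoma from the counts. Provides
    patch tiling and YOLO-dialect annotation I/O, an Otsu/contour background
    removal pipeline, a geometric candidate-cell filter (equivalent diameter and
    aspect-ratio criteria), single- and two-class object-detection evaluation
    (IoU matching, precision/recall, AP, mAP over an IoU ladder), hard-negative
    mining of false positives into a two-class dataset, dataset splitting and
    accounting, WHO grading from per-high-power-field counts, and a
    deterministic synthetic H&E-like patch generator so the whole pipeline is
    testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
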