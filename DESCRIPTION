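Package: maskwork
Title: Mask Metrics, Matching, and Transfer for Segmentation Pre-Labelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for evaluating promptable-segmentation
    pre-labelling pipelines on instance-segmentation datasets. Implements
    mask quality metrics (intersection-over-union, two-class generalized
    Dice), ground-truth-level one-to-many mask matching with F-beta scoring,
    geometric-median point-prompt generation, a hyperparameter grid-search
    harness for automatic mask generators over pluggable proposal backends,
    keypoint-based homography estimation for transferring annotations
    between overlapping images, and inter-annotator consensus statistics
    over repeated annotation rounds. Ships a deterministic synthetic-scene
    generator and mock backends so every component is exercisable without
    model weights or datasets, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    png,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
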