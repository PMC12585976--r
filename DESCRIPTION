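Package: hdmsyolo
Title: Multi-Scale Single-Stage Weed Detection Networks with Robust
    Downsampling, Partial-Convolution Aggregation and a Task-Aligned Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Composable implementation of the HDMS-YOLO single-stage
    detector family for crop/weed discrimination in field imagery. Provides
    the hierarchical robust feature downsampling modules (SRFD/DRFD built
    from slicing, grouped-convolution and max-pooling branches), the
    partial-convolution multi-scale feature aggregation block, and the
    task-aligned dynamic detection head with deformable regression and
    spatial-attention classification. An ablation-variant assembler builds
    the YOLO11n baseline and every module combination, audits exact
    parameter counts and closed-form FLOPs, and a synthetic farmland scene
    generator plus full COCO-style detection metrics (precision, recall,
    AP, mAP@50, mAP@50-95, confusion matrices) make every stage testable on
    CPU with no external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
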