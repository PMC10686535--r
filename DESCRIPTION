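Package: radrelex
Title: Two-Stage Entity and Relation Extraction for Radiology Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A trainable information-extraction toolkit that converts
    free-text radiology reports into a structured representation in two
    stages: a BiLSTM-CRF sequence labeler extracts clinical entities over a
    seven-type information model (observations, clinical findings, and five
    modifier types), and an attention-based BiLSTM binary classifier decides,
    for every admissible entity pair in a report, whether a typed modifier or
    evidence relation holds. Includes BRAT standoff and IOB2 corpus I/O,
    sentence segmentation and pluggable tokenization, a synthetic annotated
    report generator for fully reproducible benchmarks, entity- and
    relation-level evaluation (micro/per-type F1, annotation coverage,
    Cohen's kappa, major/minor mention analysis), and an end-to-end pipeline
    with seeded, deterministic training.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
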