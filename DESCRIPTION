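Package: msntx
Title: Morphometric Similarity Networks and Imaging Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-subject morphometric similarity networks (MSN) from
    regional structural MRI features, derives covariate-adjusted case-control
    regional t-maps by ordinary least squares, corrects map-level correlations
    for spatial autocorrelation with parcel-based spin permutation nulls, and
    links case-control t-maps to a regions-by-genes expression matrix through
    single-component partial least squares with bootstrap gene ranking,
    false-discovery-rate gene selection and candidate-gene spatial analysis.
    A synthetic-data module generates parcellations, cohorts and expression
    matrices with known ground truth so the whole pipeline is testable without
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
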