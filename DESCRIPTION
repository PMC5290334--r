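Package: mirisk
Title: Leukocyte miRNA Psychosis-Risk Classification and Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for miRNA-seq biomarker discovery in psychosis-risk cohorts:
    exact-match quantification of mature miRNAs in reads, top-30 quotient
    normalization with reference-group z-scoring, the CALF greedy coarse-weight
    (+1/-1) classifier with permutation and stability-selection validation,
    subsample-resampled miRNA-miRNA correlation networks with Pajek export, and
    a Smith-Waterman sequence-similarity Monte Carlo test. Includes a seeded
    synthetic cohort generator with planted group effects and tunable
    within-group correlation so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    pROC,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
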