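Package: hmvboost
Title: Predicting Tissue-Specific Versus Housekeeping Genes from Histone
    Modification Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate histone modification and variant (HMV) profiles
    to tissue/cell-type specific gene regulation. Provides Shannon-entropy
    scoring of expression specificity with entropy-threshold gene-set calls,
    nucleosome-resolved promoter, gene-body and control-region feature
    tables built from sequencing tag tracks, PCA-based grouping of marks,
    a boosting classifier over decision stumps with per-round feature
    bookkeeping, balanced-resampling cross-validated evaluation against
    control regions, cross-cell-type transfer experiments, and a synthetic
    data generator with planted class structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
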