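Package: maidflow
Title: Intensity-Dependent Fold-Change Filtering for Longitudinal
    Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired miRNA (TaqMan array Ct) and mRNA
    (microarray intensity) time-course matrices from small longitudinal
    treatment cohorts. Implements detection-limit censoring and Ct-to-linear
    conversion, cyclic loess normalization, 95 percent quantile anchoring,
    housekeeping-based relative quantification, the MAID intensity-dependent
    fold-change score with an exponential spread-versus-intensity regression
    curve, a k-of-n per-patient filter, a within-patient temporal permutation
    test for the number of filtered features, validation statistics (paired
    t-tests, Spearman concordance, single-linkage Pearson clustering),
    consensus miRNA-mRNA target-network construction, and a synthetic cohort
    generator with planted differential expression for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    igraph,
    jsonlite
Suggests:
    limma,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
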