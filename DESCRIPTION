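Package: beigesig
Title: Marker Discovery and Gene-Set Concordance for Brown and Beige
    Adipocyte Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for classifying adipose expression profiles
    by marker-set concordance. Discovers cell-type-selective marker groups
    from a three-condition expression experiment (white, rosiglitazone-induced
    beige, and classical brown adipocytes) using fold-change and t-test
    filters; quantifies qRT-PCR data by the delta-delta-Ct method; and scores
    tissue panels by gene-set correlation coefficients (Fisher-z-integrated
    Pearson correlations of an anchor gene with competing marker sets)
    compared by Z-test, with Tukey-whisker outlier screening and
    average-linkage hierarchical clustering. Includes a seeded synthetic-data
    generator with ground-truth labels so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    SummarizedExperiment,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
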