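Package: LRcrosstalk
Title: Ligand-Receptor Crosstalk Inference and Immunofluorescence Proximity
    Scoring for Tumor Microenvironment Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers confident ligand-receptor (LR) interactions from bulk
    transcriptomes by combining Spearman correlation filtering with
    pathway-topology evidence of downstream receptor activity, scores
    per-sample LR co-occurrence against immune cell-type signatures,
    stratifies samples into immune phenotypes by Ward clustering, provides
    the accompanying differential-expression post-filters and hypergeometric
    gene-set enrichment, and quantifies ligand-receptor proximity on
    multiplexed immunofluorescence images via receptor-cell detection and
    crown (annulus) fluorescence averaging. Ships seeded synthetic-data
    generators (Gaussian-copula expression cohorts, disk-and-halo IF images)
    with ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    jsonlite,
    yaml,
    tiff
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
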