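Package: cetClocks
Title: Multi-Species Epigenetic Age Clocks and Meta-EWAS for Cetacean
    Methylation Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Species- and tissue-aware elastic-net epigenetic age clocks for
    cetacean DNA methylation profiles, with leave-one-out and
    leave-one-species-out cross-validation, a two-step Stouffer z-score
    meta-analysis EWAS of age and sex across species-tissue strata, and
    hypergeometric enrichment of age-associated CpGs in chromatin states,
    polycomb-bound regions, transcription-factor binding sites and
    GREAT-style gene regulatory domains. Includes a synthetic multi-species
    methylation data generator with planted age- and sex-associated CpGs so
    the whole pipeline can be exercised and validated without array data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Regression, CrossValidation
RoxygenNote: 7.3.3
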