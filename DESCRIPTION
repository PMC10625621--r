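Package: cohortnet
Title: Comparative Mutation and Network Analysis of Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares point-mutation catalogs from two disease cohorts (for
    example de novo variants from a neurodevelopmental-disorder cohort against
    somatic mutations from tumor samples), infers disease-specific subnetworks
    from seed genes by graphlet-guided personalized PageRank with flux-based
    edge selection, identifies shared transcription factors and their common
    targets, tests those targets for pathway overrepresentation, and scores
    pathways by expression shift (mean absolute z-score) and mutation
    propensity (unique mutations per gene). Ships a synthetic-data generator
    with planted ground truth for end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
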