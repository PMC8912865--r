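Package: coexreg
Title: Regulator-Centric Gene Coexpression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene coexpression networks from TPM expression
    tables (Pearson correlation, soft-threshold power selection against a
    scale-free topology fit, signed adjacency, topological overlap), detects
    modules by adaptive cutting of the average-linkage dendrogram, and
    characterizes the modules that contain designated regulator transcripts
    (such as the fungal transcription factors xyr1 and cre1). Also constructs
    highest-reciprocal-rank (HRR) networks with band-coded edge weights,
    finds hubs and first neighbors, counts geodesics between regulators and
    target transcripts (e.g. CAZymes), and performs Fisher's exact test GO
    overrepresentation plus functional-category tallies. Ships a synthetic
    expression generator with planted modules so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
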