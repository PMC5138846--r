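Package: mdcoexnet
Title: Multi-Dimensional Co-Expression Network Analysis for Bulk RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds signed Mutual-Rank (MR) co-expression networks from
    FPKM expression matrices, overlays tissue-preferential and
    stress-differential expression states onto network views, detects
    overlapping functional modules by k-clique percolation, tests
    promoter cis-element enrichment with a permutation Z-score, performs
    Fisher-exact term enrichment with FDR control, and calls orthologue
    pairs from bidirectional BLAST tabular output using reciprocal
    top-N and e-value rules. Includes seeded synthetic-data generators
    (expression with planted co-expression modules and differentially
    expressed genes, promoters with planted motifs, BLAST hit tables)
    so the whole pipeline is testable end to end, and a pipeline driver
    that orchestrates all stages from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
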