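Package: dcnet
Title: Disease Similarity Networks from Differential Coexpression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds disease-disease similarity networks from two-condition
    gene expression cohorts using differential coexpression analysis. For
    each disease the per-gene differential coexpression statistic (dC, the
    root-mean-square change of a gene's correlations to its neighbours
    between disease and normal samples) is aggregated to pathway level,
    disease pairs are scored by partial Spearman correlation of their
    pathway-dC vectors, and significance is assessed against a
    degree-preserving gene-to-pathway membership permutation null.
    Includes downstream network statistics (within-network distance,
    category and tissue compactness, gene/drug-sharing enrichment, a
    differential-expression baseline) and a synthetic cohort generator
    with planted, group-structured coexpression decoupling for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
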