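Package: plnet
Title: Phenotypic-Linkage Network Construction and Convergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds phenotype-focused functional gene networks by weighting
    heterogeneous gene-pair evidence by its ability to predict semantic
    similarity of knockout phenotypes on a (optionally branch-restricted)
    phenotype-ontology benchmark, integrating sources with a rank-penalized
    weighted sum, and truncating to the strongest links. Downstream analyses
    include random-walk-with-restart gene prioritization with empirical
    significance, resolution-parameterized Louvain communities,
    covariate-matched permutation enrichment, circular interval-shift nulls
    for genomic loci, case/control variant burden statistics, and rank-based
    tissue-specificity enrichment. A synthetic-data module generates every
    input format with planted structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    igraph,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
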