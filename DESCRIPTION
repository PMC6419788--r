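Package: compset
Title: Compound Set Enrichment and Cluster Analysis for Screening Hits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Set-wise analytics for collections of small molecules such as
    high-throughput screening hits. Standardizes and deduplicates compound
    structures on normalized InChIKeys, computes physicochemical and
    drug-likeness descriptors (Lipinski, QED) and path-based fingerprints via
    Open Babel, calls bioassay hits by active flags, Z-score, or
    top-percentile rules, and scores Compound Set Enrichment Analysis
    (hit-enriched assays by log-likelihood ratio; target and disease
    enrichment trees by log2 odds ratio) with one-sided Fisher exact p-values
    and Benjamini-Hochberg FDR. Compound Cluster Analysis partitions a query
    set by k-means on fingerprints and links clusters to enriched annotation
    classes in an exportable cluster-class network. A deterministic synthetic
    universe generator with planted enrichments supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
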