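Package: coloclust
Title: Colocalization-First Clustering of GWAS Variants into Pathway
    Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partitions GWAS risk variants for a complex disease into
    pathway clusters using Bayesian colocalization against related traits.
    Provides Wakefield approximate Bayes factors, pairwise and multi-trait
    colocalization posteriors, sum-of-single-effects fine-mapping with
    credible sets, pleiotropy network construction with spinglass community
    detection, partitioned polygenic risk scores with association testing,
    and two-sample Mendelian randomization with Steiger directionality
    tests. Includes a synthetic-data module that generates LD matrices,
    multi-trait summary statistics with planted colocalization and cluster
    structure, and individual-level cohorts, so the full pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
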