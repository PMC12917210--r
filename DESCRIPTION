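Package: snthyro
Title: Single-Nucleus RNA-Seq Characterization Pipeline for the Pediatric Thyroid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a single-nucleus RNA-seq
    characterization workflow for pediatric thyroid tissue: quality control and
    log-normalization with fixed gene-count and mitochondrial-fraction filters,
    variance-threshold principal-component retention, shared-nearest-neighbor
    Leiden clustering across a resolution sweep with resolution-tree
    consolidation, one-vs-rest Wilcoxon marker testing with annotation filters,
    a z-score detector for rare calcitonin-producing (C) cells, a fold-ratio
    rule for subcluster-unique markers, sample-similarity statistics, and
    preranked gene-set enrichment with a permutation null. A seeded
    negative-binomial simulator generates ground-truth-annotated 10x-style
    count triplets that emulate the statistical structure of the tissue.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    data.table,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
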