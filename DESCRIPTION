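Package: trioconnect
Title: Trio Exome Variant Prioritization and Gene-Network Connectome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable pipeline for prioritizing candidate genes from parent-child
    trio exomes. Classifies variants by Mendelian inheritance mode (de novo,
    autosomal recessive, X-linked recessive) with annotation-based filtering and
    ACMG-style evidence tags, summarizes developmental brain expression (cerebellum
    versus the average of all other structures, early versus late windows), builds
    typed gene-gene evidence networks with exhaustive minimal connector-node and
    minimal transcription-factor augmentation searches, rescues orphan genes with
    predicted interactions, tests induced-edge enrichment against permutation
    nulls, and computes exact hypergeometric overlap statistics against curated
    gene panels. A synthetic-data module with planted ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
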