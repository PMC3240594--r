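Package: mirpathnet
Title: Gene Expression Signatures as Surrogates of miRNA Activity and
    Signed miRNA-Pathway Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives gene-expression signatures that act as surrogates of
    microRNA (miRNA) activity from paired miRNA/mRNA cohorts (80th/20th
    percentile high/low split, moderated t statistics, permutation-based
    robustness filtering), scores any signature on mRNA-only cohorts with a
    rank-based single-sample activation score, validates scores against
    measured miRNA expression (Spearman correlation with
    Benjamini-Hochberg control and a global label-scramble permutation
    test), assembles a signed miRNA-pathway correlation network across
    multiple cohorts (Storey q-values, pathway aggregation, cross-cohort
    concordance filtering), and characterizes its topology (clustering
    coefficient, characteristic path length, Erdos-Renyi and hierarchical
    scale-free null models, topological overlap) together with miRNA
    cotargeting and redundancy statistics (target-set overlap ratios,
    family and genomic-cluster contingency tests, global pairwise sequence
    similarity filtering). Includes a synthetic multi-cohort generator with
    planted miRNA-to-target and pathway-to-gene effects so every stage can
    be exercised against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
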