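Package: flysih
Title: Starvation-Induced Hyperactivity Phenotyping, Mixed-Model GWAS and
    Splicing Analysis for Inbred Drosophila Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative genetics of locomotor responses to
    starvation in inbred Drosophila panels such as the DGRP. Reads
    TriKinetics DAM2 activity-monitor files, computes the
    starvation-induced hyperactivity phenotype (window-wise Delta
    Activity), activity-inferred starvation resistance, broad-sense
    heritability from one-way ANOVA variance components, and a
    covariate-adjusted linear mixed-model genome-wide association scan
    with genomic relationship matrix, variant site classification and
    gene nomination. Also provides intron-excision clustering with
    percent-spliced-in (PSI) differential-splicing tests under a
    Dirichlet-multinomial model, negative-binomial differential
    expression with Benjamini-Hochberg control, and seed-deterministic
    synthetic-data generators for every input so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
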