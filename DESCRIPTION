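Package: cnvclassr
Title: Exome CNV Post-Processing, Filtering and Quantitative Pathogenicity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-processing germline copy-number variant (CNV)
    calls made from exome read depth: quality-score and in-cohort frequency
    filtering, per-sample quality control, same-allele clustering by
    reciprocal overlap, reassembly of fragmented large events, gene and exon
    annotation against one or more gene models, population structural-variant
    panel matching, microarray-detectability assessment, and a quantitative
    ACMG/ClinGen-style point engine extended with autosomal-recessive,
    X-linked, functional-evidence, complex-SV and inversion/insertion
    criteria. Includes a seeded synthetic cohort generator so every pipeline
    stage can be exercised with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
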