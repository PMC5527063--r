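Package: cernet
Title: Competing Endogenous RNA Network Inference from Multi-Class
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers competing endogenous RNA (ceRNA) networks linking
    lncRNAs, miRNAs and mRNAs across ordered physiological conditions,
    as applied to bovine liver transcriptomes spanning the dry period,
    early lactation and peak lactation. Provides differential-expression
    threshold filtering for the three RNA classes, the four-step lncRNA
    candidate filter, cis-window and trans-correlation lncRNA target
    assignment, a seed-match scanner for miRNA response elements,
    hypergeometric scoring of lncRNA-mRNA pairs over shared miRNAs with
    Benjamini-Hochberg correction, and expression-trend consistency
    pruning of the resulting network. A synthetic-data generator with
    planted ceRNA triplets provides a ground-truth test bed for the
    whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
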