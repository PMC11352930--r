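Package: loiscan
Title: Genome-Wide Imprinting and Loss-of-Imprinting Analysis from Allele-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic imprinting from allele-specific RNA-seq read
    counts with a Hardy-Weinberg-conform binomial mixture model adjusted for
    inbreeding, estimates a per-SNP degree-of-imprinting parameter with a
    boundary-corrected likelihood ratio test, and screens imprinted loci for
    loss-of-imprinting (LOI) in tumors versus normal tissue using
    integer-count binomial logistic regression with gene-level geometric-mean
    consensus and false-discovery-rate control. Includes the downstream
    clinical toolkit (differential expression, methylation M-value contrasts,
    copy-number association, Cox survival, stage-trend ANOVA), a synthetic
    cohort generator with planted ground truth for validating the full
    pipeline, and an end-to-end orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
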