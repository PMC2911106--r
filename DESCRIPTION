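Package: mztarch
Title: Comparative Analysis of Maternal and Zygotic Gene Regulatory Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare the regulatory architecture of maternally and
    zygotically expressed genes across animal genomes. Computes bespoke
    regulatory-region length metrics (5'/3' intergenic regions measured
    between coding nucleotides, first-intron measures, filtered UTR lengths,
    combined variants) from standard genome annotation; classifies genes by
    origin of synthesis (strict-maternal through strict-zygotic) from
    expression time courses, decoupled maternal/zygotic components or
    abundance ranks, and by conservation (core vs. metazoan) from
    phylogenetic presence/absence profiles; runs an iterative-percentile
    one-sided two-sample Kolmogorov-Smirnov sweep to detect
    under-representation of short regulatory regions; compares within-genome
    percentile ranks of 5' intergenic region length across 1:1 orthologs;
    and summarises maternal-to-genome length ratios across species. A
    synthetic-genome generator with planted, recoverable effects exercises
    the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    withr,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
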