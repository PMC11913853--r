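Package: triangulatr
Title: Triangulating Gene Expression, Genotype, and Behavior in a
    Two-Line Selective-Breeding Cross
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying candidate genes that
    mediate the influence of genetic variation on behavioral temperament in
    an F0-F1-F2 intercross of two selectively bred lines. Implements
    differential expression with empirical-Bayes moderation, cross-dataset
    concordance (correlation, rank-rank hypergeometric overlap, overlap
    enrichment), directional preranked gene-set enrichment, cis-eQTL mapping
    with permutation-based beta-approximated p-values and conditional scans,
    allelic fold-change estimation, founder-line segregation scoring (G'st),
    summary-data-based Mendelian randomization against behavioral QTLs, and
    a six-criterion convergence gate. Includes a fully seeded synthetic-cross
    generator (founder lines, Haldane recombination, planted eQTL/QTL
    architectures, negative-binomial counts) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    limma,
    edgeR,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
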