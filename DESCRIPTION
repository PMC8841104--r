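Package: episgsea
Title: Interaction-Sensitive Gene Set Enrichment Analysis for SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for pathway analysis of case-control SNP data that is
    sensitive to gene-gene interactions. Ranks SNPs with Relief-based
    feature importance algorithms (MultiSURF and MultiSURF*) or a
    univariate chi-square statistic, aggregates SNP scores to genes via
    positional windows and a max-statistic rule, and runs pre-ranked gene
    set enrichment with a gene-set permutation null, normalized enrichment
    scores, FDR estimation and leading-edge analysis. Includes a simulator
    of pure two-locus epistatic penetrance models with exact heritability,
    utilities for LD pruning, case-parent-trio pseudo-controls and control
    balancing, and a configuration-driven pipeline reproducing the full
    univariate-versus-Relief comparison end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
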