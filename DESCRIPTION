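Package: eqtlcross
Title: Expression QTL Mapping in Experimental Backcross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genetical-genomics studies in experimental
    livestock backcrosses: relative standard-curve quantification and
    reference-gene normalization of qPCR expression data, sex and genetic
    background effect screening, kinship-aware linear mixed model
    association scans with FDR control, construction and cis/trans
    classification of eQTL intervals, trans-eQTL hotspot detection,
    parent-of-origin (imprinting) tests from trio genotypes, and
    partial-correlation (PCIT) co-expression networks.  Includes a
    pedigreed three-backcross population simulator with planted eQTL
    architecture for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
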