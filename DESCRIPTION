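Package: epiburden
Title: Rare-Variant Interaction Burden Testing for Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Burden testing of gene-gene interactions between rare variants in
    case-control sequencing studies. For every candidate gene pair the package
    computes a functionally weighted rare-variant interaction burden in cases,
    estimates the pair's baseline burden with a recursively purified truncated
    negative-binomial regression on products of gene-level genomic features,
    and tests for enrichment with standardized deviance residuals. A two-locus
    epistasis simulator generates synthetic case-control cohorts under
    threshold, multiplicative and classic epistasis disease models and drives
    the bundled type-I-error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
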