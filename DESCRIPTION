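Package: trioscan
Title: Family-Based Association Testing with Transmission Disequilibrium
    and Two-Locus Penetrance Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for affected-sib-pair family studies of
    complex disease. Implements the transmission disequilibrium test (TDT)
    from hard genotype calls and from genotype imputation posterior
    probabilities (expected transmission counts), an HLA-stratified TDT
    with a weighted chi-square ranking statistic, multi-criteria marker
    selection and region building, case/pseudo-control two-locus
    interaction tests based on maximum-likelihood penetrance models
    (null, heterogeneity, multiplicative, general) with likelihood-ratio
    comparisons, relative quantification of qPCR expression data
    (delta-delta Ct with a multi-gene reference), and a seeded simulator
    of ascertained nuclear families for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
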