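Package: twospls
Title: Gene Regulatory Network Inference from Genetical Genomics Data
    via Two-Stage Penalized Least Squares
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from segregant
    genotype and expression data by fitting a system of structural
    equations Y = Y Gamma + X Psi + E with two-stage penalized least
    squares: ridge-regression prediction of each gene's conditional
    expectation given cis-eQTL instruments, followed by adaptive-lasso
    selection of regulators with own-cis effects unpenalized.  Includes
    cis-eQTL mapping with mean imputation and a greedy
    correlation-pruned marker filter, bootstrap edge-confidence
    assessment with the standard 80/90/95/100 percent bins, subnetwork
    extraction, and a synthetic generator of haploid-segregant
    genotypes (Haldane map function) and SEM-consistent expression with
    known ground truth so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
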