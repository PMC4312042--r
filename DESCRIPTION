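Package: serialabc
Title: Serial-Coalescent Simulation and Approximate Bayesian Computation
    for Ancient-Modern mtDNA Continuity Testing
Version: 0.1.0
Authors@R: person("Piedmont", "aDNA Analysis Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to test genealogical continuity between a heterochronous
    (ancient) mitochondrial HVR-I sample and modern population samples.
    Implements motif-notation haplotype handling for the 361-site control
    region window 16024-16384, intra- and inter-population summary
    statistics (haplotype count, segregating and private polymorphic
    sites, gene diversity, mean pairwise differences, Hudson's FST,
    allele sharing), a serial (heterochronous) coalescent simulator for
    four demographic models (continuity and discontinuity, each with an
    optional plague bottleneck), ABC model choice by acceptance-rejection
    and by local weighted multinomial logistic regression, Beaumont-style
    local-linear parameter estimation with a log-tangent transform, and a
    pseudo-observed-dataset validation suite (Type I error, power, ROC).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
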