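Package: mebvsim
Title: Forward Simulation and Marker-Based Breeding Value Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time simulation of a small diploid population to
    mutation-drift equilibrium, construction of QTL architectures with
    varying numbers of QTL and distributions of QTL variance, and three
    methods to estimate marker effects for genomic prediction: a Bayesian
    mixture model fitted by Gibbs sampling, least angle regression with
    cross-validation, and partial least squares regression with an
    iterative component search. Includes population diagnostics
    (heterozygosity, adjacent-marker linkage disequilibrium, Sved's
    expectation, QTL coefficients of determination) and an evaluation
    layer computing accuracy and mean squared error of prediction of
    marker-estimated breeding values on an evaluation generation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
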