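Package: demicabc
Title: Spatially Explicit Demic-Expansion Simulation and Approximate
    Bayesian Computation for Hunter-Gatherer/Farmer Admixture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time, spatially explicit simulation of two
    interacting population layers (hunter-gatherers and farmers) on a
    georeferenced lattice, with Lotka-Volterra competition, stepping-stone
    and long-distance dispersal, and unidirectional assimilation-type
    admixture; a backward structured coalescent conditioned on the recorded
    demography with serial (ancient-DNA) sampling, mutation and sequencing
    error; pseudo-haploid pairwise diversity summary statistics with
    partial-least-squares reduction; and two-step approximate Bayesian
    computation (demographic filter, random-forest model choice,
    GLM-adjusted rejection estimation with highest-density intervals,
    goodness-of-fit p-values, bias cross-validation and two-dimensional
    posterior queries) over six admixture scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    mgcv,
    MASS,
    mixOmics,
    ranger,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
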