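Package: ribotraffic
Title: Two-State Ribosome Traffic Simulation and Genome-Wide Inference of
    Translation Initiation Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of mRNA translation as an exclusion
    process with extended ribosomes that capture their cognate tRNA in a
    separate kinetic step before translocating. Builds codon-specific
    tRNA-capture rates from tRNA gene-copy numbers with wobble-pairing
    corrections, sweeps the initiation rate to obtain current and density
    response curves per transcript, inverts experimentally measured
    ribosome densities to estimate per-mRNA physiological initiation
    rates, classifies response curves into smooth, abrupt and hybrid
    traffic regimes, quantifies gearing (responsiveness of protein output
    to initiation changes) and saturation, runs synonymous-codon-shuffle
    experiments that separate codon arrangement from codon usage, and
    predicts protein abundance from translation efficiency. Includes an
    exact master-equation solver for small lattices used as a simulation
    oracle, and a synthetic-data generator so every stage is testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    Matrix,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
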