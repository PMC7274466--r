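Package: prionide
Title: Multi-Scale Modeling of Yeast Prion Propagation with Impulsive
    Differential Equations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the propagation of the [PSI+] prion in growing,
    asymmetrically budding yeast colonies. A bistable two-species model of
    Sup35 aggregation (soluble monomer and prion-conformation aggregate,
    with a Hill-type cooperative replication term) is coupled to impulsive
    cell-division events that dilute and asymmetrically partition
    intracellular species between mother and daughter cells. The package
    finds the equilibria of the intracellular kinetics, the periodic
    solutions of the mother-only and daughter-only lineages via their
    stroboscopic maps, classifies founder cells into full-prion, prion-free
    or sectored colony phenotypes, simulates whole colonies as binary
    lineage trees, and reproduces in-silico guanidine hydrochloride curing
    (propagon counting) experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
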