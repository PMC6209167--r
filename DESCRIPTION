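Package: spatabx
Title: Spatial Stochastic Models of Antibiotic Production, Cheating and
    Resistance in Bacterial Communities
Version: 1.0.0
Authors@R: person("spatabx", "developers", role = c("aut", "cre"),
    email = "spatabx@example.org")
Description: Simulates competition between antibiotic-producing bacteria,
    non-producing cheaters, sensitive cells and resistant cells on a
    two-dimensional lattice, together with the corresponding well-mixed
    ordinary differential equation models. The lattice engine implements
    birth, death and mutation with a Moore-neighbourhood bacteriostatic
    antibiotic field; experiment drivers reproduce outcome phase diagrams,
    replicate ensembles, evolution of the antibiotic production rate across
    multi-strain producer populations, and sweeps over the cost of
    resistance. Includes closed-form mean-field equilibria, the unstable
    producer/sensitive coexistence point and the production-rate window in
    which producers can exclude sensitive cells.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
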