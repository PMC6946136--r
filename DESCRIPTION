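Package: zetasim
Title: Resource-Explicit Reaction-Diffusion Simulation of Competing Microbial Colonies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates competition between microbial genotypes growing on a
    diffusing limiting resource on a two-dimensional lattice, with Monod
    uptake kinetics and explicit finite-difference diffusion. Implements the
    nondimensionalization that yields the natural length scale sqrt(D_R/mu1)
    and the scaled mean intercolony distance zeta, plus four evolutionary
    experiment protocols built on the engine: serial-transfer invasion of a
    faster-growing mutant (spatial and well-mixed), a competition-localization
    sweep based on Voronoi territory areas, a spatial genetic-drift assay with
    neutral founder lineages, and a drift-free grid selection assay. Includes
    a chemostat (continuous-dilution) variant and reproducible experiment
    drivers writing plain-text CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
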