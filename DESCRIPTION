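Package: poredyn
Title: Coarse-Grained Langevin Dynamics of ssDNA Translocation Through
    Nanopore-Embedded Nanochannels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the electrokinetic translocation of long single-stranded
    DNA through a rectangular nanopore embedded in a nanofluidic channel. A
    coarse-grained bead-spring chain (harmonic bonds, purely repulsive
    Weeks-Chandler-Andersen excluded volume) is advanced with an overdamped
    Euler-Langevin integrator under intramolecular, wall, electric and thermal
    forces. The nonuniform driving field is obtained from a finite-difference
    Laplace solver with insulating (Neumann) walls and electrode (Dirichlet)
    planes. Analysis tools estimate diffusion coefficients and electrophoretic
    mobility, track nanopore bead occupancy and folding states of the confined
    chain, build centre-of-mass velocity profiles, and evaluate a reduced
    analytic transport theory for entry slopes and terminal velocities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
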