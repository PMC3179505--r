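Package: pathmeta
Title: Path Collective Variable Metadynamics for Ligand (Un)Binding at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map ligand (un)binding pathways with enhanced sampling at
    desk scale: steered Langevin dynamics along a centre-of-mass distance with
    work bookkeeping, automatic path parameterization into a frameset of
    reference configurations, path collective variables S (progression) and Z
    (distance from the path) under a mean-square-deviation metric with analytic
    gradients, metadynamics with Gaussian bias deposition on (S, Z),
    free-energy-surface reconstruction with basin, barrier and binding
    free-energy analysis, hydration-coordination mapping along a pocket axis,
    and geometry monitors (distances, dihedrals, RMSD/RMSF, single-linkage
    clustering). Includes analytic toy potentials (double well, funnel pocket
    with solvent beads and an optional back-door) and a BAOAB Langevin
    integrator so every estimator can be validated against brute-force or
    closed-form free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    bio3d
Config/testthat/edition: 3
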