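Package: fepcycle
Title: Alchemical Free-Energy Analysis for Cofactor Protonation and Tautomer Equilibria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for alchemical free-energy perturbation studies
    of protonation and tautomer equilibria in protein-cofactor complexes, such
    as the pyridoxal-5'-phosphate (PLP) Schiff base in methionine gamma-lyase.
    Implements the Bennett acceptance ratio (BAR) estimator, finite-difference
    thermodynamic integration with analytic not-a-knot cubic-spline quadrature,
    length-weighted combination of derivative profiles across simulation runs,
    thermodynamic-cycle pKa and keto/enol tautomer calculations, finite-size
    corrections for charged transformations under periodic boundary conditions
    (bulk-potential shift and dielectric-scaled Wigner self-energy via Ewald
    summation), torsion force-field parametrization by iterative Boltzmann
    inversion, and geometric analysis of active-site structural ensembles.
    Includes seeded synthetic-data generators with known ground truth
    (Crooks-Gaussian work distributions, harmonic alchemy, toy Schiff-base
    coordinates, potential grids) standing in for molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
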