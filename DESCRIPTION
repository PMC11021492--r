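Package: ribbonhelix
Title: Thermodynamics, Geometry and Morphometrics of Amphiphilic Peptoid Nanohelices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing self-assembled twisted-ribbon (nanohelix)
    structures formed by short amphiphilic peptoids. Implements a
    phenomenological free-energy model for ribbon width selection governed by
    a dimensionless balance parameter kappa = gamma*l*delta/epsilon (with a
    Henderson-Hasselbalch mapping from solution pH to kappa), a builder for
    labelled bilayer ribbon coordinates on the X-ray-derived lattice, the
    twist-dihedral order parameter with handedness and pitch extrapolation,
    seeded generators for relaxation trajectories and AFM-like height maps,
    estimators that recover pitch, width, height and handedness from height
    maps, and lamellar d-spacing bookkeeping for scattering peak lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
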