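Package: fibrelease
Title: Finite-Element Models of Drug Release from Electrospun Nanofiber Implants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates diffusive release of a drug surrogate from
    poly(lactic-co-glycolide) (PLGA) nanofiber mats. Implements two coupled
    finite-element formulations on a structured hexahedral mesh: a detailed
    model in which explicit fiber polylines carry chains of analytically
    integrated radial 1D elements coupled to the 3D continuum, and a composite
    smeared finite element (CSFE) model with co-located fiber and surrounding
    concentration fields linked by nodal connectivity elements. Includes PLGA
    degradation-erosion kinetics (molecular-weight decay, porosity growth,
    effective fiber diffusivity), hydrophobic partitioning at the fiber
    surface, a seeded random generator for layered fiber mats, homogenized
    fiber diffusion tensors, mass-conservative release accounting, and a small
    command-line driver for running simulations and model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
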