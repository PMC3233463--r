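Package: qsar3d
Title: Field-Based 3D-QSAR with CoMFA/CoMSIA Descriptors and PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lattice-based three-dimensional quantitative
    structure-activity relationship (3D-QSAR) modelling of congeneric
    small-molecule series. Covers substructure-anchored rigid-body
    alignment, CoMFA steric (Lennard-Jones) and electrostatic (Coulomb)
    probe fields and CoMSIA Gaussian similarity-index fields on a regular
    lattice, partial least squares regression (NIPALS) with leave-one-out
    cross-validation and component selection, bootstrap and
    y-randomization robustness checks, the Golbraikh-Tropsha external
    validation battery including the modified r-squared (rm2) statistic,
    StDev*Coeff contour maps with OpenDX export, and a synthetic
    pseudo-receptor generator that plants a known field-activity
    relationship for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    methods,
    stats,
    utils,
    ChemmineR,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
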