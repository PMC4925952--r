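Package: trabsim
Title: Micro-Finite-Element Fracture Simulation of Idealized Trabecular Bone
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates idealized rod-like and plate-like trabecular bone
    lattices as partial-occupancy voxel models, applies age-related
    degeneration transforms (trabecular thinning, loss of vertical or
    horizontal trabeculae, two-step thinning-then-resorption at random or
    low-strain sites) with exact bone-volume-fraction targeting, and runs
    incremental displacement-controlled compression to failure with a
    voxel-based hexahedral finite element solver. Tissue failure uses an
    asymmetric principal-strain yield and crack-initiation law with
    energy-regularized (crack-band) softening, yielding apparent
    stress-strain curves, ultimate stress and fracture strain per model,
    plus tools to compare normal and degenerated architectures.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
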