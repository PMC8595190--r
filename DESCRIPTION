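Package: iopflow
Title: Intraocular Pressure After Glaucoma Drainage Device Implantation and
    Suture Occlusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical model of steady aqueous humor outflow after
    implantation of a glaucoma drainage device and after partial occlusion
    of the device tube with an intraluminal suture. Computes the
    dimensionless shape factor of the tube cross-section (closed form for a
    concentric suture, a finite-difference Poisson solve for a wall-touching
    suture), the generalized Hagen-Poiseuille hydraulic resistance of the
    tube, the post-implant intraocular pressure from a lumped outflow
    network (ciliary inflow, trabecular pathway, implant plus filtration
    bleb), and forward/inverse solvers that predict the intraocular pressure
    reached with a given suture or the suture diameter achieving a target
    pressure, across the trabecular-open, mixed and trabecular-closed flow
    regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
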