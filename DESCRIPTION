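Package: orbishock
Title: Thin-Shell Finite-Element Simulation of Impulsive Orbital Trauma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the dynamic response of the bony orbital walls to an
    impulsive strike on the inferior orbital rim, the loading scenario behind
    blowout fractures and posttraumatic orbital emphysema.  Provides a
    parametric generator for an average adult orbit as a triangulated thin
    shell, flat-facet shell finite elements (constant-strain membrane with
    discrete Kirchhoff bending), explicit central-difference and implicit
    Newmark transient integration, and post-processing that quantifies the
    outward-then-retrograde displacement wave of the orbital floor, recovers
    von Mises surface stresses, and flags fracture-threshold exceedance.
    Includes analytic verification benchmarks, Gmsh MSH 4.1 and legacy VTK
    mesh exchange, and a config-driven reproduction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
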