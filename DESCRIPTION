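Package: corticofold
Title: Multi-Field Finite-Element Simulation of Cortical Folding Driven by
    Neural Cell-Type Dynamics
Version: 0.1.0
Authors@R:
    person("Corticofold", "Developers", email = "corticofold@example.org",
           role = c("aut", "cre"))
Description: Simulates cortical folding in the developing brain on a
    two-dimensional quarter-annulus section.  Finite-growth hyperelastic
    mechanics (neo-Hookean, plane strain, multiplicative decomposition of the
    deformation gradient) is coupled to a four-species advection-diffusion-
    reaction system describing radial glial cells, intermediate progenitor
    cells, outer radial glial cells, and neurons.  Includes a structured
    quadrilateral mesh generator, a monolithic Newton time stepper with
    streamline artificial diffusivity for advection-dominated transport, a
    gestational-week timeline with a five-phase cell-lineage ledger, and
    post-processing utilities: outer-contour extraction, local gyrification
    index, normalized radial density profiles, per-zone cellular
    deconvolution, temporal peak detection, a parameter-sweep driver, and
    VTK/CSV/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
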