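Package: atherosim
Title: Free-Boundary Simulation of Atherosclerotic Plaque Growth Driven by the
    LDL-HDL Profile
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates early atherosclerotic plaque formation in the arterial
    intima as a coupled system of reaction-diffusion-advection equations for
    lipoproteins, free radicals, cytokines and cells (macrophages, T cells,
    smooth muscle cells, foam cells), closed by a Darcy pressure law on an
    evolving two-dimensional domain whose lumen-facing boundary moves with the
    tissue velocity under a curvature (cell adhesion) condition. Provides P1
    Galerkin finite elements with backward-Euler time stepping on structured
    mapped triangulations, scenario runs returning plaque-weight trajectories,
    an (LDL,HDL) risk-map sweep with region classification, and a Latin
    hypercube / partial rank correlation coefficient (PRCC) global sensitivity
    pipeline. All user-facing functions take and return tidy data structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    lhs,
    jsonlite
Config/testthat/edition: 3
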