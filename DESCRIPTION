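Package: stokeslets
Title: Generalized Hydrodynamic Friction for Active Surfaces and Microswimmers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale simulation of shape-changing active surfaces and
    microswimmers at zero Reynolds number. Surfaces are discretized as clouds
    of regularized Stokeslets (with the Blake image system for a no-slip
    wall), surface tractions are obtained from a dense resistance solve, and
    principal shape changes are treated as generalized coordinates with
    conjugate generalized hydrodynamic friction forces. The symmetric,
    positive-definite generalized friction matrix is precomputed on
    coordinate grids, serialized, and interpolated (Fourier series on
    periodic coordinates) so that force-balance equations of motion can be
    integrated fast. Built-in applications include rigid-body and
    free-swimmer solves (three-sphere swimmer), and a wall-anchored cilia
    pair with a synthetic three-dimensional beat pattern: driving-force
    calibration, in-phase and anti-phase synchronization, one-cycle Lyapunov
    exponents, and far-field scaling of hydrodynamic coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
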