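Package: qtrgext
Title: Quasi Time-Reversible Grassmann Extrapolation of SCF Density Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates self-consistent field (SCF) initial-guess density matrices
    for Born-Oppenheimer molecular dynamics by extrapolating previous converged
    densities on the Grassmann manifold. Implements the quasi time-reversible
    extrapolation scheme with Coulomb-matrix descriptors and Tikhonov-regularized
    least squares, alongside the plain Grassmann extrapolation and dissipative
    extended-Lagrangian (XLBO) baselines. Ships a charge-self-consistent
    tight-binding toy model, an NVE velocity-Verlet driver, and energy-stability
    diagnostics (short-time fluctuation, long-time drift, SCF iteration
    statistics) so that guess quality can be measured end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
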