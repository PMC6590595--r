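Package: reactlin
Title: Linearization Accuracy Analysis for Mass-Action Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well a Taylor linearization approximates a
    nonlinear mass-action reaction network around a steady state. Builds
    bilinear ordinary differential equation models from reaction lists,
    computes analytic state and input Jacobians, locates steady states with a
    stiff integrator plus Newton refinement, and co-simulates the linearized
    and nonlinear dynamics through an augmented agreement system whose error
    component tracks the linearization error directly. A Monte Carlo workflow
    perturbs base inputs with bounded multiplicative noise and aggregates mean
    relative error, mean squared error and error/response standard-deviation
    ratios over input samples, at the level of all states or of a readout
    subset. Validity diagnostics cover hyperbolicity of the anchor point,
    local and global Lyapunov exponents via variational integration,
    contraction-mapping checks, second-order (Hessian) error indicators and
    input-sensitivity comparison between fixed points. A layered
    receptor-ligand cascade generator produces synthetic signaling networks in
    the spirit of the canonical WNT pathway for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
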