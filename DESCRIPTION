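Package: ssfit
Title: Parameter Estimation for ODE Models with Steady-State Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood parameter estimation for ordinary
    differential equation models of perturbation experiments in which the
    initial condition is the (parameter-dependent) steady state of the
    unperturbed system. Implements a hybrid optimization method that
    retracts iterates onto the steady-state manifold by combined
    simulation and Newton-Raphson polishing, and a simulation-based
    method that integrates a continuous analogue of gradient or
    Newton-type descent stabilized by a manifold retraction term, next to
    unconstrained and equality-constrained baselines. Includes forward
    sensitivity analysis, steady-state sensitivities, Fisher information,
    a multi-start harness with likelihood-ratio convergence
    classification and steady-state consistency diagnostics, BIC/AIC
    model comparison, synthetic perturbation-data generation, and a small
    model zoo (conversion process, NGF-ERK, Raf/MEK/ERK with and without
    negative feedback).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
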