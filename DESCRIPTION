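Package: microdisk
Title: Reaction-Diffusion Modelling of a Michaelis-Menten Micro-Disk Biosensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Steady-state modelling of an enzyme-film micro-disk biosensor
    governed by Michaelis-Menten kinetics. Solves the coupled nonlinear
    reaction-diffusion boundary-value problem for the dimensionless substrate
    and hydrogen-peroxide concentration profiles with a damped-Newton
    finite-difference solver, evaluates published closed-form series
    approximations (HPM, MADM, HAM) and the saturated zero-order limit,
    trains a single-hidden-layer perceptron surrogate by Levenberg-Marquardt
    with validation-based early stopping, and scores fits with MAD, Theil's
    inequality coefficient, Nash-Sutcliffe efficiency and multi-run
    stability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
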