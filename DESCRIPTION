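Package: dkrmr
Title: Steady-State Modelling of Lipase-Catalysed Dynamic Kinetic
    Resolution in Hollow-Fibre Membrane Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the steady-state reaction-diffusion-convection model of
    lipase-catalysed dynamic kinetic resolution (DKR) of racemic ibuprofen
    ester in a hollow-fibre membrane bioreactor. Implements the coupled
    nonlinear two-point boundary value problem for the dimensionless (S)- and
    (R)-ester concentration profiles across the membrane, closed-form
    homotopy-perturbation (HPM) series solutions, an independent collocation
    solver of the bvp4c type, local and mean integrated effectiveness factors
    with several closed-form and quadrature variants, series validity-region
    scanning with linear frontier fitting, and normalized parameter
    sensitivity analysis. Parameter sets, bulk states and all results are
    plain tibbles, with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
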