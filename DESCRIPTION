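Package: superchild
Title: Population-Based (Super-Child) Vitamin A Tracer Kinetics and Retinol
    Isotope Dilution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for evaluating the population-based
    ("super-child") design used to estimate vitamin A total body stores (TBS)
    and whole-body retinol kinetics in children.  The package implements a
    delay-containing linear compartmental model of oral tracer kinetics,
    generates calibrated synthetic cohorts of theoretical children with known
    kinetic parameters, builds composite geometric-mean plasma tracer data
    sets under extensive, reduced, and sparse two-sample sampling protocols,
    fits the composite curves by weighted nonlinear least squares with nested
    model selection, derives time-variant retinol isotope dilution (RID)
    coefficients from the fitted population model, and evaluates group and
    individual TBS predictions against the known values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    lhs,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
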