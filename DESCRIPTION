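Package: notchsim
Title: Delta-Notch Boundary-Formation Model of the Drosophila Large Intestine
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Delta-Notch dependent boundary-cell patterning in the
    Drosophila embryonic large intestine. Each cell on a hexagonal lattice
    carries a three-variable ordinary differential equation for Delta,
    inactive Notch and active Notch, coupled to its neighbours by trans
    binding of Delta to Notch and shaped by cis inhibition of Notch
    conversion by Delta. The package provides the lattice and dorsal/ventral
    prepattern, stiff integration of the full system with an analytic
    Jacobian, closed-form equilibria and Routh-Hurwitz stability analysis of
    the two-cell reduction, boundary-cell classification, parameter sweeps
    over the Delta and Notch production rates, per-cell parameter
    perturbation studies with replicate statistics, and noisy Notch
    production experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
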