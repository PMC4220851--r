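Package: stoichTumour
Title: Stoichiometric Tumour-Immune Dynamics in a Potassium-Limited Environment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical analysis of a stoichiometric predator-prey
    model of tumour-immune cell interactions in a closed, potassium-limited
    environment. The tumour grows by a Droop cell-quota law under Liebig's
    minimum principle (carbon versus potassium limitation), immune recruitment
    efficiency depends on the tumour's potassium quota, and the immune pool is
    subject to tumour coercion and a constant treatment influx. The package
    implements the continuous ODE system, its discrete exponential-map analogue
    with frozen per-capita rates, equilibrium location and stability
    classification (eigenvalues, Jury criterion, nullcline slopes), forward
    invariant-region and potassium mass-balance audits, immunoediting phase
    classification (elimination, equilibrium, escape), and one-parameter
    bifurcation sweeps with period detection and maximal Lyapunov exponents.
License: MIT + file LICENSE
Encoding: UTF-8
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
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
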