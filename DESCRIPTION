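Package: gcntherm
Title: Stochastic Thermodynamics of Active Particles Driven by Gaussian
    Colored Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the one-dimensional
    Gaussian-colored-noise (GCN) model of active Brownian particles: an
    overdamped particle driven by an Ornstein-Uhlenbeck "active bath" with
    persistence time tau and active diffusivity D. Provides seeded
    Euler-Maruyama ensemble integrators in both the position-activity and
    position-velocity representations; estimators of the local thermodynamic
    fields (density, kinetic temperature, heat-flux density, medium entropy
    flux) and of the global heat and entropy budgets, including the
    generalized Clausius inequality with the non-uniform local bath
    temperature theta(x) = D/(tau*Gamma(x)); closed-form unified-colored-noise
    (UCNA) and Fox approximations; a perturbative small-persistence expansion
    of the local mean-square velocity with its quartic worked example; and an
    independent spectral solver of the associated Kramers equation with
    reversible/dissipative current decomposition and entropy budget, used to
    cross-validate simulation and theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
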