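Package: pnaokin
Title: Transient and Steady-State Kinetics of the Pnao Catalytic Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mass-action simulation and kinetic analysis of the catalytic cycle
    of pseudooxynicotine amine oxidase (Pnao), a flavoenzyme that oxidizes
    pseudooxynicotine and is reoxidized by the cytochrome c protein CycN rather
    than by molecular oxygen. Provides a kinetic-scheme builder and stiff ODE
    integrator for the reductive and oxidative half-reactions, Beer-Lambert
    projection of concentration trajectories onto stopped-flow absorbance
    traces, seeded synthetic-data generators with instrument dead time, noise
    and detector saturation, multi-exponential trace fitting with BIC phase
    selection, secondary (linear, hyperbolic, constant) analyses of observed
    rates, Michaelis-Menten steady-state fitting with the two-cytochrome
    stoichiometric correction, a rate-limiting-step consistency analysis, and
    simulation plus linearized Nernst analysis of xanthine/xanthine-oxidase
    redox titrations against an indicator dye.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
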