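Package: clotcore
Title: Reduced Thin-Film Kinetics of Thrombin and Fibrin Generation Under Venous Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-order model of blood coagulation on a collagen/tissue-factor
    surface under venous flow. The clot core is treated as a well-mixed 15-micron
    thin film in which seven Michaelis-Menten activation reactions, linearized at
    constant plasma zymogen levels, drive an eight-state stiff ODE cascade with
    reversible two-site thrombin binding to fibrin (the antithrombin-I activity of
    the E-domain and gamma'-chain sites), first-order protease inhibition, and
    diffusive escape of free species. Includes derived elution-flux observables
    (thrombin-antithrombin and fragment F1.2), in silico scenario transforms
    (fibrin polymerization block, hemophilia, FXIa-feedback knockout,
    gamma'-fibrinogen scaling, escape-time sensitivity), a two-dimensional
    finite-volume convection-diffusion-reaction companion model of thrombin
    loading into and elution from a porous fibrin zone in a flow channel, fixture
    generators that couple the ODE output to the transport model, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
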