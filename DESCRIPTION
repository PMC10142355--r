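Package: hergng
Title: Deterministic Nucleation-and-Growth Model of hERG Potassium
    Channel Gating
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the gating of the hERG (Kv11.1) cardiac potassium
    channel with a deterministic nucleation-and-growth (Avrami) kinetic
    model in which the stepwise outward movement of the four S4 voltage
    sensors drives a progressive opening of the channel.  A four-equation
    ODE system integrated by classical fourth-order Runge-Kutta yields the
    normalized gating charge S(t); Boltzmann steady-state curves and an
    empirical linear fast-inactivation damping factor convert S(t) into
    outward and inward potassium current families under step-voltage
    protocols, and the time derivative of S gives the gating current.
    Includes a synthetic-trace generator and Levenberg-Marquardt recovery
    of the model's free parameters (the aggregation rate constant
    k_N*k_R^2, the deactivation decay constant k_h and an amplitude
    scale) from current traces, plus a small command-line interface and
    CSV trace input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
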