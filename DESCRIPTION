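Package: setpointadapt
Title: Setpoint State-Space Models of Visuomotor Adaptation with an
    Explicit Aiming Strategy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, fitting and behavioral analysis of setpoint
    state-space models of trial-by-trial visuomotor-rotation adaptation
    when participants are instructed to use an explicit re-aiming
    strategy. The model family separates a slowly adapting internal
    model, driven by the error between cursor feedback and the strategic
    aiming location, from a flexible strategy state adjusted by target
    error, with direct feedthrough of the strategy to the reach.
    Includes an experimental-protocol schedule builder, a synthetic
    cohort generator emulating the three landmark-availability groups,
    bounded Nelder-Mead fitting with a participant-resampling bootstrap,
    and estimators for peak drift, aftereffect and exponential washout
    rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
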