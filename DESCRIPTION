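Package: aoxkinetics
Title: Kinetics of Adsorbable Organic Halogen Formation in Chlorine
    Dioxide Bleaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the power-law kinetic analysis of adsorbable organic
    halogen (AOX) formation when phenolic (vanillyl alcohol) and non-phenolic
    (veratryl alcohol) lignin model compounds react with chlorine dioxide
    under bleaching conditions. Implements the rate law dW/dt =
    A*exp(-E/RT)*[H+]^a*[ClO2]^b*[C]^c, initial-rate extraction from AOX
    time series, reaction-order estimation by log-log least squares over
    one-factor-at-a-time sweeps, Arrhenius regression of log k on 1/T for
    the activation energy and pre-exponential factor, deterministic
    forward simulation of AOX curves with reagent depletion, a synthetic
    factorial data generator for parameter-recovery studies, and an
    end-to-end fitting pipeline with CSV/JSON interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
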