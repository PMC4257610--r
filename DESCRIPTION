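Package: mosquitodyn
Title: Temporal Dynamics of Adult Mosquito Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the temporal structure of daily adult
    mosquito abundance records and for simulating the processes that
    generate it. Provides discrete Fourier power spectra on the period
    grid T = N*dt/i with peak detection, autocorrelation and partial
    autocorrelation analysis with weekly-subsampling degradation
    experiments, a stochastic cohort-based individual life-cycle
    simulator for Aedes vexans and Culiseta melanura with
    weather-driven development, survival, oviposition and a
    rainfall-dependent activity (trappability) layer, estimation of the
    activity ratio from observations, and least-squares calibration and
    simulation of Ricker and Gompertz-logistic density-dependent
    population models. Synthetic weather and abundance generators allow
    every analysis to run self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    zoo,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
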