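Package: nitrocycle
Title: Kinetic Box Model of a Global Abiotic Planetary Nitrogen Cycle
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulator for the abiotic cycling of nitrogen on an
    Earth-like planet over 4.5 Gyr. Nitrogen in three redox classes (N2,
    reduced NHx, oxidized NOx) is exchanged among atmosphere, ocean, marine
    sediments, continental crust, and upper/lower mantle through
    parameterized abiotic fluxes: cometary delivery, impact and lightning
    fixation, hydrothermal reduction, sediment adsorption on a Freundlich
    isotherm, subduction and continental accretion, erosion, volcanic
    degassing, and mantle mixing. Air-sea N2 partitioning follows Henry's
    law; time stepping is explicit Euler with per-pool flux limiting and
    instantaneous re-equilibration. Includes random-initial-condition
    ensembles with collapse-time statistics, time-averaged mass balances,
    steady-state parameter sweeps, named scenario presets, YAML scenario
    files, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
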