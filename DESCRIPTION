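Package: cesim
Title: Dynamic One-Dimensional Simulation of Chiral Capillary
    Electrophoresis with a Sulfated Cyclodextrin Selector
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled electromigration-diffusion dynamics of weak
    bases interacting with a highly charged chiral selector (1:1 complexation)
    in a capillary filled partially with selector-containing background
    electrolyte. Provides a charge-balance acid-base and complexation
    equilibrium solver under electroneutrality, effective-mobility isotherms
    and zero-mobility transition concentrations, a scenario library of initial
    column states for partial-filling configurations, an explicit finite-volume
    transport engine at constant voltage, and observables (current traces,
    peak metrics, departure/arrival/reversal events, focusing diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
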