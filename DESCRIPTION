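Package: dismodgp
Title: Incidence-Prevalence-Mortality Modelling of General-Practice Registry Data
Version: 0.1.0
Authors@R:
    person("Registry", "Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating incidence and prevalence of chronic diseases
    from aggregated general-practice (GP) registration-network tables. Derives
    observed incidence density and point prevalence from stratified counts,
    checks their mutual consistency by projecting a hypothetical birth cohort
    through a discrete-time illness-death model, fits a joint
    incidence-prevalence-mortality (DisMod) model by maximum likelihood with a
    misclassification fraction for prevalent cases recorded as incident,
    attaches parametric-bootstrap confidence intervals to directly standardized
    rates, and pools network-specific estimates by DerSimonian-Laird
    random-effects meta-analysis on the log scale. A patient-level synthetic
    registry generator emulates episode-of-disease and episode-of-care
    registration with annual contact probabilities and a lookback window, so
    the whole pipeline is testable without confidential data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
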