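Package: catpop
Title: Stratified Demographic Modelling of Community Cat Populations Under
    Trap-Neuter-Return Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating national free-roaming ("community") cat
    populations from stratified municipal census ratios and for projecting
    their dynamics over multi-decade horizons under trap-neuter-return (TNR)
    sterilization policies. Implements a binomial litter-frequency model
    modulated by a reproductive utilization rate, a truncated discrete
    Gaussian litter-size model, stage-structured (kitten/adult x
    sterilized/unsterilized) annual projection with demographic
    stochasticity, catastrophes, abandonment and adoption flows, and
    carrying-capacity ceilings. Includes a synthetic municipal-census
    generator so the full pipeline is testable without administrative data,
    and both a stochastic Monte-Carlo engine and a deterministic
    expected-value engine for cross-validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
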