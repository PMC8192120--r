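Package: slc6sim
Title: Voltage-Dependent Kinetic Models of Monoamine Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov-state kinetic simulator and analysis pipeline for the
    transport cycles of the plasmalemmal monoamine transporters DAT, NET and
    SERT (SLC6 family). Represents alternating-access reaction schemes with
    voltage-dependent (symmetric-barrier) and ligand-coupled rate constants,
    integrates the master equation under patch-clamp style application
    protocols, and converts state occupancies into measurable signals:
    coupled and uncoupled membrane currents and fluorescence substrate
    uptake. Ships calibrated DAT, NET and SERT model fixtures, virtual
    experiments (concentration-response, current-voltage, two-pulse turnover
    recovery, intracellular ion sweeps), the curve families used to analyse
    them (rectangular hyperbola, Boltzmann, line, mono-exponential, nested
    F-tests), Gibbs free-energy profiles along reaction loops, and a
    generator of synthetic two-channel patch-fluorometry recordings with a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
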