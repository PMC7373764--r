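Package: haldane
Title: Haldane Substrate-Inhibition Kinetics for Microbial Phenol
    Biodegradation
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Tools for analysing batch-culture phenol biodegradation
    kinetics. Converts spectrophotometric readings (4-aminoantipyrine
    phenol assay, OD600 biomass) to concentrations via linear
    calibrations, estimates specific growth and degradation rates from
    time-courses by log-linear regression, fits the Haldane
    substrate-inhibition model mu(S) = mu*.S/(Ks + S + S^2/Ki) to
    (S0, rate) points by multistart nonlinear least squares, and reports
    the derived critical substrate concentration Sm = sqrt(Ks.Ki) and
    true maximum rate mu*/(1 + 2.sqrt(Ks/Ki)). Includes a seeded batch
    bioreactor simulator for parameter-recovery validation and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
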