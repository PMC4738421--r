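Package: mitoquality
Title: Time-Dependent Master-Equation Model of Mitochondrial Quality During Cell Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the probability distribution of discrete mitochondrial
    quality states during cell aging with a fully time-dependent master
    equation. Five quality-changing processes are modelled: metabolic and
    proteinaceous fission/fusion with Hill-equation rates, the coupled
    mitophagy/biogenesis recycling cycle, binomial repair of missing quality
    units, binomial quality loss from activity-dependent internal oxidative
    stress, and stochastic external damage. Each process carries an
    exponential decay or growth law for its probability over the cell's
    lifetime. The package provides an explicit Euler integrator with a strict
    probability-conservation guard, quality metrics (average quality, mean
    absolute deviation, inactive fraction), named scenario presets for
    reproducible simulation experiments, YAML configuration files, tidy CSV
    trajectory output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
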