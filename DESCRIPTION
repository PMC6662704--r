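Package: sedch4
Title: Sediment Methane Formation Kinetics in Tropical Reservoirs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates net methane (CH4) formation rates in anoxic reservoir
    sediment from long-term headspace incubations and models their decline
    with sediment age. Converts raw vial observations (headspace mixing
    ratios, pressures, volumes) into dissolved plus gaseous CH4 and CO2
    amounts via the ideal gas law and Henry's law, assigns each rate a
    sediment age from an age-depth model, fits per-core exponential decay
    models with a slope-based transition age to low background formation,
    integrates CH4 formation over a 100-year reservoir lifetime with yearly
    layer deposition, and fits a global ln(Age) x TN prediction model with
    lognormal back-transformation bias correction. A seeded synthetic-data
    generator reproduces the statistical structure of a three-reservoir
    incubation study so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
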