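Package: hydromix
Title: Mixing Power and Conversion Analysis for High-Solids Enzymatic Hydrolysis
Version: 0.1.0
Authors@R:
    person("hydromix", "maintainers", email = "maintainers@hydromix.invalid",
           role = c("aut", "cre"))
Description: Quantitative analysis of mixing effects in high-solids enzymatic
    hydrolysis of pretreated lignocellulose in a stirred tank reactor. Couples
    a power-law rheology model of the fibre slurry (consistency index as a
    power function of the water-insoluble-solids content, Metzner-Otto average
    shear rate) to an impeller power-number correlation (P0 = K1/Re + K2) to
    compute apparent viscosity, impeller Reynolds number, power draw and
    cumulative mixing energy along a glucan-to-glucose conversion trajectory.
    Includes least-squares fitting of the power correlation from motor-power
    measurements, enzyme-dosing and slurry-dilution stoichiometry, an
    anchor-calibrated synthetic conversion generator with seeded measurement
    noise, a second-order response surface of conversion versus energy input
    and time, CSV/JSON input-output surfaces and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
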