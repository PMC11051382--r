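Package: ventgas
Title: Thermochemical Equilibrium and Kinetics of Graphite-Saturated Volcanic Gas
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models nitrogen-rich magmatic gas interacting with graphite-saturated
    crust, predicting gas-phase mixing ratios of nitriles (HCN, HC3N) and
    isonitriles (HNC, estimated CH3NC) as functions of added graphite,
    temperature, pressure and elemental composition.  Provides NASA-7 polynomial
    thermochemistry for an H/C/N/O species set, an element-potential gas-phase
    equilibrium solver with graphite condensation clamped at its saturation
    vapor pressure, a reversible reaction-network integrator whose reverse rates
    enforce detailed balance, scenario drivers for graphite-addition and
    temperature/pressure sweeps with an oxygen-fugacity (QFM) diagnostic, and
    seeded synthetic fixtures with independent brute-force equilibrium oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
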