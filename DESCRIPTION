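Package: glassdyn
Title: Dielectric and Calorimetric Analysis of Amorphous Drug Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the physical state of amorphous
    pharmaceuticals, in particular drug / mesoporous-silica composites,
    from broadband dielectric spectroscopy (BDS) and differential
    scanning calorimetry (DSC). Dielectric loss spectra are deconvolved
    into Havriliak-Negami / Cole-Cole relaxation processes plus DC
    conductivity; relaxation maps are built with Vogel-Fulcher-Tammann
    and Arrhenius fits, yielding the kinetic glass transition
    temperature, fragility, and a coupling-model classification of
    secondary relaxations. Master curves are constructed by
    time-temperature superposition and described with the
    Kohlrausch-Williams-Watts stretched exponential evaluated in the
    frequency domain. DSC thermograms are analyzed for the glass
    transition step, crystallization-exotherm onsets and Gaussian
    multi-peak melting deconvolution, feeding composition-series
    analyses: monomolecular loading capacity extrapolation,
    crystallization-onset trends and polymorph area fractions. Seeded
    synthetic-data generators emulate the statistical structure of both
    experiments so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
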