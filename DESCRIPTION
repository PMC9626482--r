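Package: plasmadose
Title: Dose-Rate Assessment for Low-Temperature Plasma from DNA-Damage Modelling
Version: 0.1.0
Authors@R: person("Plasmadose", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A modelling framework for estimating the effective dose rate
    (Gy/s) delivered by low-temperature atmospheric-pressure plasma (LTP)
    sources from the extent of DNA damage they induce. Provides a seeded
    synthetic design-of-experiments (DoE) generator for plasma-induced DNA
    damage and a synthetic dose vs. DNA-damage literature database; a
    physics-guided neural network (PGNN) regressor with a monotonicity
    (physical-loss) penalty plus classical baseline regressors, trained with
    leakage-safe SMOTE-style oversampling inside cross-validation; an
    irradiation-time finder that inverts a fitted damage model; dose-rate
    extraction via dose / t_irr with 1-D K-means clustering and Tukey outlier
    treatment; parameter sweeps over voltage and frequency; and deviation
    metrics against configured reference dose rates, orchestrated by a
    reproducible seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
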