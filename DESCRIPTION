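Package: cuflux
Title: Kinetic Modeling of Copper Homeostasis in Budding Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to build, calibrate and interrogate an ordinary-differential-
    equation model of cytosolic copper homeostasis in Saccharomyces cerevisiae.
    The package constructs the canonical 10-component, 25-reaction trafficking
    network (transcription factors MAC1/ACE1, metallothionein, a collective
    pool of other copper proteins, the CTR importer and the labile copper
    pool), fits Hill cooperativity to transcription-factor titration data and
    recalibrates the ligand axis to the labile-pool scale, converts measured
    copper group concentrations into apo/holo protein concentrations across a
    seven-condition nutrient-copper titration, decomposes the stoichiometric
    null space into nonnegative basic pathways to solve steady-state fluxes,
    back-calculates apparent rate constants and fits logistic (soft Heaviside)
    regulation to the reactions whose constants trend with copper, and
    integrates the assembled stiff dynamical system through annealing,
    perturbation, nutrient-step, knockout and nutrient-sweep experiments. A
    synthetic-data generator with known ground truth supports end-to-end
    parameter-recovery validation.
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
    jsonlite,
    knitr,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
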