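Package: phenomicStress
Title: Phenomic Analysis of Heat and Drought Stress Experiments at Anthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for factorial heat-by-drought phenomics experiments on
    flowering crops. Implements the Farquhar-von Caemmerer-Berry (FvCB)
    model of C3 photosynthesis with an A/Ci curve fitting engine that
    estimates Vcmax, electron transport rate (ETR), triose phosphate use
    (TPU) and day respiration with per-point limitation assignment;
    three-view RGB image segmentation and plant/flower volume estimation;
    per-trait factorial linear mixed-model ANOVA (genotype x heat x drought
    with a random block); and genotype-level trait correlation matrices
    with hierarchically clustered heatmaps. A synthetic-data generator
    emulates the full experimental design (deficit-irrigation water
    balance, trait time courses, gas-exchange curves, plant images, fresh
    weight and seed yield) with known ground truth, so every analysis
    stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    lme4,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
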