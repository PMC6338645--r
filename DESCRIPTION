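Package: nrf2ampk
Title: Delayed NRF2-AMPK Negative Feedback and Autophagy Under Oxidative Stress
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the antioxidant master regulator NRF2
    (SKN-1 in Caenorhabditis elegans) shuts down autophagy during prolonged
    oxidative stress by repressing transcription of its own upstream activator
    AMPK (aak-2). The package provides an ordinary-differential-equation model
    of the stress -> AMPK -> NRF2 -> (delayed AMPK repression) -> autophagy
    network with genotype/knockdown perturbations, constraint-based calibration
    of one parameter set per experimental system (human cell line, worm) to
    published fold-changes, a hazard model mapping simulated autophagosome
    trajectories to paralysis fractions in C. elegans stress assays, IUPAC
    consensus scanning for ARE/SKN-1 binding sites with cross-species
    conservation reporting, seeded synthetic-data generators (densitometry
    time courses, puncta cohorts, paralysis cohorts, motif-planted sequences),
    and the study's statistical procedures (pooled t tests with Bonferroni
    correction, one-way ANOVA with Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
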