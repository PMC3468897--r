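Package: larvatrack
Title: Multiwell Larval Zebrafish Behavior Tracking and Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, video tracking and statistical analysis of larval
    zebrafish behavior in multiwell plates. Provides a synthetic-data
    generator for bout-like locomotion with a circadian rhythm, tap-evoked
    startle swims and dorsal-pigmentation rendering; reference-subtraction
    centroid tracking of multiwell image stacks; spontaneous-activity,
    circadian, startle, habituation and inclusion-filter metrics;
    visual-background-adaptation (VBA) pigmentation classification with
    Mendelian ratio goodness-of-fit; and a statistics layer with pooled and
    Welch t-tests, Cohen's d, and mixed repeated-measures ANOVA with
    Greenhouse-Geisser correction and partial eta squared. A file-based
    pipeline runner orchestrates simulate, track, metrics and stats stages
    into reproducible, seed-deterministic runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
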