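Package: filatrack
Title: Growth Quantification of Filamentous Cyanobacteria in Microcapillary Micrographs
Version: 0.1.0
Authors@R:
    person("Filatrack", "Developers", email = "filatrack@example.org",
           role = c("aut", "cre"))
Description: Image-analysis pipeline for quantifying growth of filamentous
    cyanobacteria (Oscillatoria) cultivated in fluoropolymer microcapillary
    strips. Detects capillary lanes in brightfield micrographs, segments
    filaments, converts filament areas to cell counts and lengths using
    SEM-derived cell morphometry, re-identifies filaments across weekly
    timepoints, and estimates size-group-dependent rates of increase of
    population (dN/dt) by least squares with one-way ANOVA and pairwise
    t-test group comparisons. Includes a synthetic micrograph generator
    with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    clue,
    jsonlite,
    png,
    truncnorm,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
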