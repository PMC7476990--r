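Package: egmorph
Title: Unipolar Electrogram Morphology Analysis Under Gap-Junction Uncoupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and automated morphological analysis of paced unipolar
    contact electrograms recorded with a 4x4 grid mapping catheter. Provides a
    seeded synthetic generator in which epicardial conduction is modelled as
    shortest-path wavefront propagation over a two-dimensional velocity field
    whose magnitude and heterogeneity depend on a cell-to-cell coupling factor,
    a current-source forward model for the extracellular potentials, automated
    beat segmentation and landmark detection, extraction of nineteen
    time-domain morphology features plus stimulus-to-(-dV/dt)max activation
    latency, baseline-versus-uncoupled comparison statistics (Welch t-tests and
    percent change), and four-parameter logistic dose-response fitting of the
    conduction delay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    igraph,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
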