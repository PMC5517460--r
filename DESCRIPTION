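Package: nirsconn
Title: Scanning-Duration Stability of fNIRS Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for assessing how resting-state functional near-infrared
    spectroscopy (fNIRS) scanning duration affects the stability, between-run
    reproducibility, and test-retest reliability of functional connectivity and
    graph-theory network metrics. Includes a synthetic two-run multichannel
    cohort generator with known ground-truth connectivity and reliability,
    modified Beer-Lambert law conversion, PCA+ICA artifact rejection with
    temporal/spectral/spatial noise criteria, zero-phase band-pass filtering,
    duration binning, Pearson and maximum lagged cross-correlation connectivity,
    sparsity-thresholded binary and weighted network metrics (nodal/global/local
    efficiency, betweenness, clustering) with AUC summaries, and stability /
    reproducibility / intraclass-correlation evaluation across durations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
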