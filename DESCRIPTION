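Package: circuitnet
Title: Network Activity Analysis for Calcium-Imaging Movies of Neural Circuitoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for population calcium-imaging movies of
    stem-cell-derived neural networks ("circuitoids"). Tiles a movie into a
    lattice of oval regions of interest, extracts smoothed delta-F/F traces,
    separates signal from noise by principal-component analysis with
    scree-elbow component selection, calls network bursts against a
    noise-calibrated threshold, merges burst positions across regions into a
    catalog of distinct network events, and summarises each movie by a
    directed burst-sequence graph whose "network complexity" score measures
    how far the regions deviate from a single shared burst sequence. Also
    provides rhythmicity (interval coefficient of variation), burst frequency
    and amplitude statistics, pairwise-correlation synchrony, and the group
    comparison statistics used with these metrics. A ground-truthed synthetic
    movie generator renders calcium-kernel transients on configurable
    subnetwork partitions so every stage can be validated without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
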