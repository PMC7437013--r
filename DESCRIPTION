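Package: alphasw
Title: Alpha-Band EEG Functional Connectivity and Small-World Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the relationship between resting-state
    alpha-band (8-12 Hz) EEG functional connectivity and small-world network
    organization. Implements three undirected connectivity estimators --
    magnitude-squared coherence, the imaginary part of coherency, and
    synchronization likelihood with time-delay embedding -- together with
    proportional density thresholding of connectivity matrices, binary
    small-world metrics normalized by degree-preserving (Maslov-Sneppen) null
    models, Erdos-Renyi reference graphs, and the study-level Pearson
    correlation analysis with Bonferroni control. A synthetic multichannel
    generator with known coupling structure, lag, volume-conduction-style
    instantaneous mixing and Watts-Strogatz topology provides ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
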