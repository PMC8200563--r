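Package: dendrodev
Title: Developmental Morphometry of Basal Dendritic Arbors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of developmental change in neuronal
    dendritic morphology from SWC reconstructions. Parses and validates
    SWC files, computes a fifteen-feature morphometric vector per neuron
    (arbor lengths, topology counts, partition asymmetry, contraction,
    remote bifurcation amplitude, principal-axis extents, fractal
    dimension, convex-hull field area), assembles labelled feature
    matrices with outlier removal, z-scoring and correlation pruning,
    classifies each feature as stable or varying across age groups via
    an L1 distance between normalized histograms, and runs dual PCA
    (stable versus varying feature subsets), Ward hierarchical
    clustering on the components covering 95 percent of variance, and
    SVM-based validation. Includes a stochastic generator of synthetic
    basal-dendrite cohorts so the whole pipeline is testable without
    archive downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    ape,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
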