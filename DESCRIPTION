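Package: dcvwalk
Title: Heterogeneous Random Walk Analysis of Dense-Core Vesicle Transport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models dynein-driven retrograde transport of dense-core vesicles
    as a discrete random walk whose per-vesicle movement probability is drawn
    from a beta density. Provides the resulting beta-binomial displacement
    distribution and beta-negative-binomial first-passage-time distribution
    with closed-form moments, maximum-likelihood fitting of the heterogeneity
    parameters from step-count samples, a Monte-Carlo trajectory simulator, a
    kymograph track-processing pipeline (unit conversion, deduplication,
    directional classification, displacement-at-lag and first-passage
    extraction), and a generator of labelled synthetic kymograph track files
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
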