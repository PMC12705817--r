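Package: ematract
Title: Behavioral Tractography of Ecological Momentary Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Temporal symptom-network analysis of ecological momentary
    assessment (EMA) panels. Estimates cross-sectional and time-lagged
    associations between momentary psychological states with random-intercept
    mixed-effects regressions, prunes them by Benjamini-Hochberg false
    discovery rate control, embeds the resulting network in two dimensions by
    principal component analysis of the adjacency matrix, and assembles a
    two-layer three-dimensional temporal network. Interlayer shortest paths
    are summarized by four anchor coordinates and clustered into bundles of
    similar behavioral trajectories; bundle trajectories of two populations
    are compared with a subject-permutation null on the ratio of between- to
    within-group distances. Includes clinical-interview dimensionality
    reduction (PCA, k-means subgrouping, group statistics) and a synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    withr
Suggests:
    lme4,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
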