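Package: microtraj
Title: Trajectory Geometry and Dimension Diagnostics for Microbial
    Community Ordinations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing longitudinal microbial community data
    through the geometry of ordination spaces. Computes Bray-Curtis and
    weighted UniFrac dissimilarities and a robust centred log-ratio
    (rCLR) transform; embeds samples with principal coordinates analysis,
    Sammon mapping, non-metric multidimensional scaling, and robust
    Aitchison PCA (masked low-rank matrix completion) across a sweep of
    dimensionalities; quantifies per-replicate trajectory direction
    (cosine similarity), smoothness, and linearity; diagnoses the
    resolution/homogenisation trade-off with signal-to-noise ratio,
    k-nearest-neighbour distance statistics, and the Hopkins clustering
    tendency statistic; and runs permutation-based PERMANOVA (global,
    per-soil, pairwise, and dimension-swept) together with alpha
    diversity estimators. A seeded synthetic microcosm generator
    (Dirichlet-multinomial counts over a factorial soil x treatment x
    time design with an inoculant taxon decaying from spike to residual
    abundance) makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS
Config/testthat/edition: 3
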