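Package: microscale
Title: Spatial Scaling and Assembly Analysis of Soil Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the spatial scaling of microbial communities
    sampled under a nested quadrat design: taxa-area relationships (power and
    logarithmic models) with permutation slope comparison, co-occurrence
    networks under Spearman correlation thresholds and the node-area
    relationship with breakpoint (tipping point) detection, the Sloan neutral
    community model, the normalized stochasticity ratio, Levins niche breadth,
    alpha and beta diversity, environmental heterogeneity and Mantel tests.
    Includes a synthetic nested-community generator with known ground truth
    (migration rate, niche strength, guild correlation structure) so that every
    stage of the pipeline can be validated without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vegan,
    igraph,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
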