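Package: hostislands
Title: Plant Families as Islands: Apparency, Phylogenetic Isolation, and
    Utilization Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats plant families as islands in the sense of island
    biogeography and models the presence-absence of consumers (herbivores,
    pathogens, human uses) on them. Fits binomial logit models of
    utilization probability against plant apparency (family species or
    genus counts, distribution area) with a Wald G statistic and derived
    apparency thresholds; measures phylogenetic signal of binary
    utilization traits with the Fritz-Purvis D statistic against
    permutation and Brownian-threshold null models on a dated family-level
    phylogeny; and relates host breadth to apparency thresholds, baseline
    utilization probability and phylogenetic signal with cross-group
    regressions. Includes utilizer ratios, minimum phylogenetic distance
    to "mainland" families, randomized binomial baselines, a
    synthetic-data generator emulating the assumed data structure, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
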