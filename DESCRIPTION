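Package: nuegrn
Title: Gene-to-Phenotype Regulatory Network Inference for Nitrogen Use Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline linking gene expression to nitrogen use
    efficiency (NUE) phenotypes in crop field trials. Computes derived NUE
    phenotype metrics (N uptake, NUEg, NUEb, potential index), detects
    trait-correlated weighted co-expression modules with eigengene merging
    and hub-gene filtering, infers a transcription-factor-to-target
    regulatory network by per-target random-forest importance ranking,
    validates and prunes the network against gold-standard edges via
    precision/recall and AUPR with permutation significance, and prioritizes
    master regulators by hypergeometric overlap Z-scores with a local
    GO-style enrichment and subnetwork extraction. Ships a seeded synthetic
    data generator emulating a multi-variety two-by-two
    nitrogen-by-water field design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
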