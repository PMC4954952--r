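Package: ricemqtl
Title: Metabolite QTL Mapping, Hotspots and Epistasis in a Rice RIL Population
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis pipeline for replicated multi-trait
    (metabolomic) studies of biparental recombinant inbred line populations,
    modelled on the Lemont x Teqing rice design. Provides broad-sense
    heritability and genotype-by-experiment variance decomposition,
    Haley-Knott interval mapping with genome-wide permutation thresholds,
    stepwise multi-QTL model selection with 1.5-LOD support intervals,
    sliding-window QTL hotspot detection with permutation nulls,
    hotspot-marker additive and pairwise-epistasis Type III ANOVA models,
    per-line coefficient-of-variation traits for mapping stochastic
    variation, and a seeded synthetic-data generator that emulates the
    study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
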