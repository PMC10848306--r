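Package: rumenTransmit
Title: Mother-Offspring Transmission and Taxa-Function Stability of Rumen Bacteria
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for vertical transmission of rumen bacteria
    between mother cows and their offspring. Provides partition-wise
    (heritable versus nonheritable taxa) Bray-Curtis compositional
    similarity, genotype-taxon and genotype-VFA association testing with
    Benjamini-Hochberg false discovery control, Spearman co-abundance
    networks with edge thresholding, and a taxa-function stability engine
    that perturbs community compositions, projects them through a
    gene-content matrix, and fits the attenuation/buffering power law
    f = t^b / e^a. A calibrated synthetic paired-cohort generator
    reproduces the study cohort's summary statistics so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), vegan, vcfR, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
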