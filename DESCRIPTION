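Package: trophmeta
Title: Multilevel Meta-Analysis of Plant Genetic Diversity Effects Across
    Trophic Levels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-synthesis machinery for meta-analyses of plant
    genetic (genotypic) diversity effects on plants, plant antagonists and
    natural enemies of herbivores. Computes bias-corrected standardized
    mean differences (Hedges' g) with unbiased sampling variances, fits
    multilevel mixed-effects meta-regression models by restricted maximum
    likelihood with species random effects under an optional phylogenetic
    correlation structure and observation-within-study nesting, compares
    nested models by likelihood-ratio tests, models effect-size trends over
    the number of added genotypes by generalized least squares with an
    exponential variance function, fits piecewise structural equation
    models (d-separation basis sets, Fisher's C) over bi- and tri-trophic
    effect-size subsets, and diagnoses publication bias via residual
    regression tests and the Rosenthal fail-safe number. A synthetic-data
    generator reproduces the hierarchical structure the analyses assume so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    nlme,
    withr
Config/testthat/edition: 3
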