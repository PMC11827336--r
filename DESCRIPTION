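Package: cptEval
Title: Genomic Evaluation of Cloned Progeny Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and genomic evaluation of cloned progeny trials (CPT)
    in forest tree breeding. Provides a synthetic generator for clonally
    replicated progeny populations laid out in alpha-lattice field designs
    across multiple sites; marker and sample quality control with
    Mendelian-error based pedigree verification and correction; pedigree
    (tabular method) and genomic (additive and dominance) relationship
    matrices with numerator blending; a dense average-information REML mixed
    model engine supporting supplied covariance kernels, separable AR1 x AR1
    spatial residuals and heterogeneous site residuals; stage-wise and
    single-stage genomic evaluation with heritabilities, prediction-error
    based accuracies and response to selection; and a replicate-subsetting
    study that quantifies how reducing ramets per ortet changes heritability,
    accuracy and clone rankings.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr
Encoding: UTF-8
Config/testthat/edition: 3
RoxygenNote: 7.3.3
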