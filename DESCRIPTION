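Package: pvep
Title: Personalized Variant Effect Prediction Across Haplotype Backgrounds
Version: 0.1.0
Authors@R:
    person("pvep", "maintainers", email = "pvep@example.org", role = c("aut", "cre"))
Description: Quantifies how genetic background modulates computational
    predictions of clinical variant effects. Injects focal clinical variants
    (missense, splice-altering, UTR) into personalized haplotypes built from
    phased cohorts, scores wild-type and mutant sequences through a pluggable
    scorer-adapter interface, and characterizes the resulting per-variant
    score distributions: reference representativeness, normality and modality
    (variational Bayes Gaussian mixtures), ridge-regression variant
    sensitization maps, non-additive background-by-clinical interaction
    tests with FDR control, structural contact enrichment, and benchmarking
    of population-averaged scores against annotation tables. Ships
    deterministic toy scorers and a synthetic phased-cohort generator so the
    whole pipeline runs at desk scale without external models or data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    data.table,
    jsonlite,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
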