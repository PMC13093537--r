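Package: imconn
Title: Individual Molecular Connectomes from Regional PET SUVR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds single-subject perturbation networks ("individual molecular
    connectomes") from regional PET standardized uptake value ratios by adding one
    subject to a normative reference group and renormalizing the change in the
    partial-correlation connectome. Provides connectome fingerprinting of single
    subjects across timepoints, gradient-boosted estimation of per-edge
    contributions to diagnostic discrimination, a Box-Cox-transformed connectome
    alteration score, permutation-calibrated group comparisons and longitudinal
    mixed-effects models, volume-weighted composite SUVR baselines with repeated
    classification and cognitive-prediction benchmarks, leave-one-gene-out
    transcription networks with gene-set fold enrichment, and a synthetic-cohort
    generator that emulates the statistical structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
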