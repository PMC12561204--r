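Package: codchain
Title: Chain-of-Decisions Models for Personalized Medication at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage chain-of-decisions framework for personalized
    medication in chronic disease: (1) severity prediction from fused
    tabular and image-derived patient features with gradient-norm-driven
    dynamic modality weighting, (2) medication-combination efficacy scoring
    with an edge-aware graph transformer over multi-attribute medication
    graphs built on prescription co-occurrence priors and random-walk PPI
    embeddings, and (3) contrastive patient-regimen matching with cosine
    confidence ranking and HIT@k evaluation. Includes a synthetic-cohort
    generator with planted, recoverable signal so every stage can be
    validated without access to clinical data, plus a minimal reverse-mode
    automatic-differentiation engine on which all stage models are trained.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    MASS,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
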