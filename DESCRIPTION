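Package: matrisig
Title: Matrisome Expression Signatures for Survival Stratification
Version: 1.0.0
Authors@R: person("Matrisig", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derivation and evaluation of prognostic matrisome RNA
    signatures from small-replicate two-condition expression arrays.
    Implements rank-product differential expression with permutation
    significance, matrisome gene-set filtering with mouse-to-human
    ortholog mapping, fold-change centroid construction, centroid
    correlation and weighted median-split patient stratification,
    Kaplan-Meier, log-rank and multivariate Cox proportional-hazards
    evaluation, and multiple-testing-based refinement of a full
    centroid to a compact reversed-sign signature.  Includes seeded
    synthetic-data generators for fibroblast arrays with planted fold
    changes and for tumour cohorts with a latent signature-like
    expression state carrying a proportional-hazards effect, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
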