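Package: bgpseq
Title: Deep Bayesian Gaussian Processes for Clinical Code Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Uncertainty-aware risk prediction from longitudinal clinical
    code sequences. Implements a transformer sequence encoder with summed
    code/age/segment/position embeddings, mean-field Gaussian (Bayes-by-
    Backprop) variational posteriors over the embedding and classifier
    weights, and Gaussian-process classification heads: a sparse variational
    GP with free inducing points and a structured-kernel-interpolation
    (KISS) GP with additive one-dimensional grids. Monte-Carlo weight
    sampling yields per-patient predictive distributions, evaluated with
    bootstrap ranking metrics, confidence-rejection curves, calibration
    bands across sampled models, a KL-divergence statistic contrasting the
    predictive-uncertainty distributions of correct and incorrect
    predictions, and embedding-entropy rankings. A seeded synthetic cohort
    generator with a planted token-driven risk process makes the whole
    pipeline runnable without access to restricted health-record data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
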