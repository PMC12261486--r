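Package: seqadme
Title: Sequential ADME Multi-Task Learning for Drug-Likeness Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pharmacokinetics-ordered sequential multi-task training of
    molecular encoders on grouped ADME (absorption, distribution, metabolism,
    excretion) endpoints, with gradient-conflict surgery (PCGrad) and
    missing-label masking; a task-dependency analysis based on the task
    improvement rate (TIR); and a drug-likeness classifier trained on frozen
    ADME-informed embeddings with a balanced-metric evaluation battery (MCC,
    F1, AUPRC).  Includes endpoint-table aggregation with train-set target
    normalization and stratified cross-validation folds, and a synthetic-data
    generator that plants an A-to-D-to-M-to-E latent dependency chain for
    desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
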