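Package: neurocaption
Title: Feature-Guided Generation of Text Descriptions from Brain Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear decoding of layerwise semantic features from brain-activity
    matrices with ridge regression and nested cross-validation, followed by
    iterative, proposal-model-guided evolution of descriptive text whose
    features are aligned with the decoded features. Includes voxelwise
    encoding models with per-voxel layer selection, Deming-regression parity
    comparison, a database-search baseline, caption-similarity evaluation
    (feature correlation, BLEU-4, METEOR, ROUGE-L, CIDEr, BERTScore),
    identification analyses, word-order shuffling diagnostics,
    pseudo-log-likelihood fluency scoring, Self-BLEU diversity, and a fully
    synthetic toy world (order-sensitive feature extractor, bigram proposal
    model, simulated linear brain responses) for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
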