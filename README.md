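# neurocaption

Generating text descriptions of semantic content from brain-activity
matrices, for researchers studying linear decoding of language-model
features from fMRI and feature-guided text generation.

## What it does

The package implements a two-stage pipeline:

**Stage 1 — feature decoding.** Layerwise semantic features of text
(token-averaged embeddings, one vector per model layer) are decoded from
multivoxel patterns with ridge regression,

y&#770; = X W + b,  W = argmin ||Y − XW||² + λ||W||²,

with λ selected per layer from 10 values log-spaced between 10 and 10,000
by run-grouped nested cross-validation (6 outer × 5 inner folds). Voxelwise
encoding models (features → voxels) rank voxels, select each voxel's best
layer from training-side folds, and drive voxel selection; Deming regression
converts paired model accuracies into angular deviations from parity.

**Stage 2 — description optimization.** Starting from a noninformative
`<unk>` token, candidates evolve by masking (span replacement and mask
interpolation), unmasking (categorical proposal-model fills), and selection
by the length-penalized score

s = r · l^(−α),  α = 0.1,

where r is the candidate-to-target feature correlation averaged over layers
and l the token count. A beam of 5 candidates, 5 masked variants per
candidate and 5 fills per variant bound each step at 130 scored candidates;
100 iterations × 5 restarts produce the final description. A
database-search baseline, an untrained uniform-proposal control, and an
evaluation battery (feature correlation, BLEU-4, METEOR, ROUGE-L, CIDEr,
BERTScore, discriminability with Cohen's d, identification curves,
word-order shuffling, pseudo-log-likelihood fluency, Self-BLEU) complete
the pipeline. A fully synthetic toy world (order-sensitive deterministic
extractor, bigram proposal model, linear brain simulator) makes everything
runnable without external data or model weights.

## Worked example

```r
library(neurocaption)

ex       <- make_toy_extractor(units = 64, seed = 1)
corpus   <- generate_toy_corpus(toy_world_config(seed = 2))
proposal <- fit_toy_proposal(corpus)

cap <- corpus$entries[[1]][1]           # "turtle pushes rabbit"
res <- optimize_description(ex$embed(cap), ex, proposal,
                            optimizer_config(seed = 3, stop_r = 1 - 1e-9))
res$description
#> [1] "turtle pushes rabbit"
res$score$r
#> [1] 1
max(res$trace$pool_size)
#> [1] 130
```

The optimizer reconstructs the caption exactly from its own model-derived
features: the layer-averaged feature correlation reaches exactly 1 (an exact
string match implies identical features), and no optimization step ever
scores more than the 130-candidate search-width bound.

The full brain-in-the-loop path runs through `run_pipeline()` (stages
`simulate`, `extract`, `train`, `decode`, `optimize`, `evaluate`,
`db-search`), or from a shell via the thin wrapper
`inst/cli/neurocaption.R`:

```sh
Rscript inst/cli/neurocaption.R simulate --config run.yaml --seed 1
```

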