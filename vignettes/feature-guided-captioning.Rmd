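---
title: "Feature-guided generation of text descriptions from brain activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-guided generation of text descriptions from brain activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocaption)
```

## The problem and the model

Multivoxel fMRI patterns evoked by viewing (or recalling) a visual scene
carry semantic information that can be read out linearly. neurocaption
implements a two-stage pipeline that turns such patterns into text:

1. **Feature decoding.** Layerwise semantic features of text — token-averaged
   embeddings, one vector per layer of a language model — serve as the
   intermediate space. Ridge regression decoders (one linear readout per
   feature unit, one model per layer) map brain activity into that space.
   The regularization coefficient is chosen per layer from 10 values
   log-spaced between 10 and 10,000 by maximizing the mean held-out
   correlation across all units, inside a run-grouped nested
   cross-validation (6 outer folds, 5 inner folds). Voxelwise encoding
   models (the reverse map) rank voxels by how well the feature set
   predicts them, select each voxel's best layer from training-side folds
   only, and supply the voxel-selection step (up to 50,000 best-predicted
   voxels in a whole-brain analysis).

2. **Description optimization.** Starting from a single noninformative token
   (`<unk>`), candidate descriptions evolve through iterated
   *masking* (replacing each span of up to 3 words with a mask, or
   interpolating a mask at any position, re-applied up to 2 extra times for
   multi-mask variants), *unmasking* (a masked-language-model-style proposal
   model fills each sampled masked variant with categorical draws,
   left-to-right for multiple masks), and *candidate selection*: every new
   and original candidate is scored by

   \[ s = r \cdot l^{-\alpha}, \]

   where \(r\) is the Pearson correlation between candidate and target
   features averaged over layers, \(l\) the token count and
   \(\alpha = 0.1\) the length-penalty exponent. The top 5 candidates
   survive each of the 100 iterations; 5 restarts guard against local
   optima and the best-scoring final candidate wins. With 5 beam
   candidates, 5 masked variants each and 5 fills per variant, at most
   `5*5*5 + 5 = 130` candidates are scored per step.

### The length penalty

The score form deserves a note. A *penalty* on length must shrink the score
of longer candidates, so the default `penalty_form = "decay"` uses
\(s = r\,l^{-\alpha}\); the literal product form \(s = r\,l^{\alpha}\)
(which rewards length for positive \(r\)) is available as
`penalty_form = "printed"` for comparison. With \(\alpha = 0\) the ranking
reduces to raw \(r\). For negative \(r\) a multiplicative penalty shrinks
scores toward zero — mildly favouring longer poor candidates — which beam
competition resolves in practice; the formula is kept as defined.

Token counting uses the feature extractor's own tokenizer with special
tokens excluded; candidate features can be re-normalized with the decoder
training statistics (`stats` argument) so that candidates and targets are
compared in the same normalized space in which the decoders were trained.

## The synthetic toy world

Nothing in the package requires downloads: the `synthdata` functions
generate every input.

* `generate_toy_corpus()` builds agent–verb–patient(-modifier) scenes
  (60 videos x 5 caption paraphrases by default, split 80/20 train/test,
  6 runs). The first two pairs of videos are argument swaps of each other
  ("turtle pushes rabbit" vs "rabbit pushes turtle"), so some caption pairs
  share a word multiset while differing in meaning — word order carries
  relational information by construction.
* `make_toy_extractor()` is a deterministic two-layer feature extractor:
  layer `bag` averages seeded-hash word loadings (order-insensitive, like
  shallow embeddings); layer `seq` averages position-weighted loadings of
  adjacent word bigrams (order-sensitive, like deep layers). Determinism is
  exact — word loadings are drawn from an RNG seeded by a hash of the word —
  so repeated extraction is bit-identical and an exact string match yields a
  feature correlation of exactly 1.
* `fit_toy_proposal()` fits an add-k-smoothed bigram model exposing
  masked-position fill distributions (left and right context, unigram
  backoff) — the stand-in for a pretrained masked language model.
  `uniform_proposal_model()` is the untrained control.
* `simulate_brain()` mixes the concatenated layer features through a fixed
  random matrix and adds i.i.d. Gaussian noise (300 voxels, 6 round-robin
  runs by default).

What the toy world deliberately lacks: hemodynamics, spatially correlated
voxel noise, subject variability, and the scale and ambiguity of natural
captions. Passing tests therefore demonstrate the *mechanics* of the
pipeline — parameter recovery, order sensitivity, search behaviour — not
performance on real fMRI data, which additionally depends on the quality of
real language-model features and measurement noise.

## A worked run

```{r, eval = FALSE}
ex <- make_toy_extractor(units = 64, seed = 1)
corpus <- generate_toy_corpus(toy_world_config(seed = 2))
proposal <- fit_toy_proposal(corpus)

cap <- corpus$entries[[1]][1]
res <- optimize_description(ex$embed(cap), ex, proposal,
                            optimizer_config(seed = 3, stop_r = 1 - 1e-9))
res$description   # recovers `cap` exactly, r = 1
```

The full brain-in-the-loop path (`simulate` → `train` → `decode` →
`optimize` → `evaluate`) is wired through `run_pipeline()`, with a thin
command-line wrapper in `inst/cli/neurocaption.R`.

## Evaluation battery

* `similarity_score()` scores a description against a video's reference
  captions under feature correlation, BLEU-4 (epsilon smoothing, 0.1 on zero
  match counts; orders without hypothesis n-grams dropped from the geometric
  mean), exact-match METEOR, ROUGE-L (\(\beta = 1.2\)), CIDEr (n ≤ 4,
  video-level TF-IDF, x10 scaling) or BERTScore against a pluggable token
  embedding provider (with optional IDF-weighted precision). Per-video
  aggregation is the mean for feature correlation and BERTScore and the max
  for the n-gram metrics.
* `discriminability()` (correct-video minus mean incorrect-video score) with
  `discriminability_d()` pooled-SD effect sizes; `identify_by_text()`
  accuracy-vs-set-size curves (exhaustive at set size 2, resampled above,
  chance `1/n`); `identify_pairwise_by_features()` for decoded-feature
  identification; `generalizability_angle()` with leave-one-pair-out
  jackknife SE.
* `shuffle_words()` / `shuffle_impact_report()` probe word-order
  sensitivity with up to 1000 distinct word-level permutations (all words or
  nouns only via an injected tagger; one-noun descriptions are skipped
  explicitly), `pseudo_log_likelihood()` scores fluency by whole-word
  masked scoring, and `self_bleu()` measures within-group diversity.
* `fdr_bh()`, `cohens_d()` and `bootstrap_ci()` (percentile, 10,000
  resamples by default) back the statistical summaries.

## Numerical choices and degenerate inputs

* Ridge fits use the SVD of the column-centered design; the intercept is
  always included and unpenalized. `lambda = 0` on a rank-deficient design
  falls back to the minimum-norm solution with a warning.
* Regularization ties break to the smallest grid value; best-layer ties
  break to the shallowest layer; relative depth is
  `(layer - 1)/(n_layers - 1)`.
* The Deming regression error-variance ratio is fixed at 1; zero variance on
  both axes is an error.
* Feature units with near-zero training SD (below `1e-8`) are flagged and
  mapped to zero rather than dividing by a vanishing SD.
* A candidate whose feature vector is constant in some layer contributes a
  correlation of 0 for that layer.
* Candidate ties in the beam break by shorter token count, then
  lexicographically; duplicate candidate strings are removed before scoring.
* Mask fills are sampled without replacement for the first mask of a variant
  (distinct words whenever the support allows); subsequent masks take one
  conditioned draw per branch.
* `stop_r` is an optional convergence threshold: once the best candidate's
  layer-averaged correlation reaches it (e.g. exactly 1 when reconstructing
  from model-derived features), remaining iterations and restarts are
  skipped. The default (`NULL`) runs the full budget.

## Problem sizes used in the shipped checks

The test suite exercises the pipeline at desk scale, chosen to keep a full
run in minutes while leaving all mechanisms intact: decoding recovery uses
120 samples x 300 voxels x 64 units across 6 runs; reconstruction and
shuffle benchmarks use 20 captions of at most 6 words; the proposal-model
contrast uses 20 paired targets at 30 iterations x 2 restarts; the
search-width audit covers 1,000 optimization steps. The identification
chance calibration draws 10,000 resamples of 100 candidates under a random
scorer.

## Known limitations

* The bundled extractor and proposal model are deterministic toys; adapters
  for real language models must satisfy the `feature_extractor` /
  `proposal_model` contracts (determinism, finite outputs, normalized
  categorical distributions) but are not shipped.
* METEOR is the exact-match variant (no stemming or synonymy); BLEU
  smoothing is the epsilon method recorded above.
* The database-search baseline scores the whole database in memory; it is
  sized for desk-scale databases (hundreds to thousands of captions).
* Encoding-model voxel selection uses best-layer accuracy (not mean-layer);
  this choice is exposed through the `encoding_map` contents.
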