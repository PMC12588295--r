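# Shared fixtures, built in code at test time.

tw_extractor <- function(units = 32, seed = 11) make_toy_extractor(units, seed)

tw_corpus <- function(seed = 5, ...) generate_toy_corpus(toy_world_config(seed = seed, ...))

# lexicon noun tagger over the default toy vocabulary
tw_noun_tagger <- function() {
  nouns <- toy_world_config()$vocabulary$agents
  function(words) words %in% nouns
}

# small aligned features/brain pair with known linear structure
tw_linear_system <- function(n = 60, units = c(8, 8), n_voxels = 60,
                             noise_sd = 0.02, n_runs = 6, seed = 42) {
  lf <- with_seed(seed, layer_features(
    list(bag = matrix(rnorm(n * units[1]), n),
         seq = matrix(rnorm(n * units[2]), n))))
  model <- linear_brain_model(sum(units), n_voxels = n_voxels,
                              noise_sd = noise_sd, n_runs = n_runs,
                              seed = seed)
  list(features = lf, brain = simulate_brain(lf, model), model = model)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
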