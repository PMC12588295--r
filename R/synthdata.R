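#' Toy-world configuration
#'
#' Defines the synthetic study conditions used throughout the package's
#' tests: a small vocabulary partitioned into agents, verbs, patients and
#' modifiers, from which agent-verb-patient(-modifier) captions are built so
#' that word order carries relational meaning ("bird eats snake" vs
#' "snake eats bird").
#'
#' @param n_videos Number of videos (scenes).
#' @param captions_per_video Paraphrases per scene.
#' @param n_runs Scanner runs the simulated samples are split into.
#' @param seed Root seed; named substreams (corpus/mixing/noise) derive from it.
#' @param test_fraction Fraction of videos held out as the test split.
#' @param vocabulary List with character vectors `agents`, `verbs`,
#'   `patients`, `modifiers`.
#' @return List of class `toy_world_config`.
#' @export
toy_world_config <- function(n_videos = 60, captions_per_video = 5, n_runs = 6,
                             seed = 1, test_fraction = 0.2,
                             vocabulary = NULL) {
  nouns <- c("bird", "snake", "dog", "cat", "horse", "monkey", "rabbit",
             "turtle", "fox", "mouse")
  vocabulary <- vocabulary %||% list(
    agents = nouns,
    verbs = c("eats", "chases", "watches", "carries", "follows", "pushes"),
    patients = nouns,
    modifiers = c("quickly", "slowly", "quietly", "outside", "indoors", "gently"))
  words <- unlist(vocabulary, use.names = FALSE)
  if (anyDuplicated(unique_w <- unique(words)) > 0) stop_user("vocabulary words must be unique")
  structure(list(n_videos = n_videos, captions_per_video = captions_per_video,
                 n_runs = n_runs, seed = seed, test_fraction = test_fraction,
                 vocabulary = vocabulary, words = unique_w),
            class = "toy_world_config")
}

#' Generate a synthetic caption corpus
#'
#' Scenes are agent-verb-patient triples with per-caption modifiers. The
#' first two pairs of videos are argument swaps of each other (same word
#' multiset, different order), providing order-distinct contrasts by
#' construction. Captions within a video are paraphrases: the bare triple
#' plus modifier-extended variants.
#'
#' @param config A [toy_world_config()].
#' @return A [caption_corpus()] whose `"scenes"` attribute holds the
#'   generating agent/verb/patient table.
#' @export
generate_toy_corpus <- function(config = toy_world_config()) {
  stopifnot(inherits(config, "toy_world_config"))
  voc <- config$vocabulary
  with_preserved_rng({
    set.seed(config$seed + 101L)
    n <- config$n_videos
    agent <- character(n); verb <- character(n); patient <- character(n)
    i <- 1
    while (i <= n) {
      a <- sample(voc$agents, 1); p <- sample(setdiff(voc$patients, a), 1)
      v <- sample(voc$verbs, 1)
      agent[i] <- a; verb[i] <- v; patient[i] <- p
      # make videos 2 and 4 argument swaps of videos 1 and 3
      if (i %in% c(1, 3) && i + 1 <= n) {
        agent[i + 1] <- p; verb[i + 1] <- v; patient[i + 1] <- a
        i <- i + 1
      }
      i <- i + 1
    }
    scenes <- data.frame(video_id = sprintf("vid%03d", seq_len(n)),
                         agent = agent, verb = verb, patient = patient,
                         stringsAsFactors = FALSE)
    # drop accidental duplicate scenes by regenerating their verb
    key <- paste(agent, verb, patient)
    while (anyDuplicated(key)) {
      j <- which(duplicated(key))
      for (k in j) {
        swap_of <- if (k %in% c(2, 4)) k - 1 else NA
        verb[k] <- sample(voc$verbs, 1)
        if (!is.na(swap_of)) verb[swap_of] <- verb[k]
      }
      key <- paste(agent, verb, patient)
    }
    scenes$verb <- verb
    entries <- vector("list", n)
    for (k in seq_len(n)) {
      base <- paste(agent[k], verb[k], patient[k])
      mods <- sample(voc$modifiers, max(0, config$captions_per_video - 1),
                     replace = config$captions_per_video - 1 > length(voc$modifiers))
      caps <- c(base, if (length(mods)) paste(base, mods))
      entries[[k]] <- caps[seq_len(config$captions_per_video)]
    }
    # swap pairs share modifiers so their caption word multisets match
    for (k in c(2, 4)) {
      if (k <= n) {
        mods_prev <- sub("^\\S+ \\S+ \\S+ ?", "", entries[[k - 1]])
        base <- paste(agent[k], verb[k], patient[k])
        entries[[k]] <- ifelse(nzchar(mods_prev), paste(base, mods_prev), base)
      }
    }
    names(entries) <- scenes$video_id
    n_test <- max(1, round(config$test_fraction * n))
    test_ids <- scenes$video_id[sample.int(n, n_test)]
    split <- stats::setNames(ifelse(scenes$video_id %in% test_ids, "test", "train"),
                             scenes$video_id)
    corpus <- caption_corpus(entries, split = split)
    attr(corpus, "scenes") <- scenes
    corpus
  })
}

#' Deterministic order-sensitive toy feature extractor
#'
#' Two layers emulate the shallow-vs-deep contrast of language-model
#' embeddings: layer `"bag"` averages seeded-hash unit loadings per word
#' (order-insensitive), while layer `"seq"` averages position-weighted
#' loadings of adjacent word bigrams (order-sensitive, as the deeper layers
#' of a language model are). Both are exactly deterministic: a word's loading
#' is drawn from an RNG seeded by a hash of the word string, so the same text
#' always maps to bit-identical vectors.
#'
#' @param units Units per layer.
#' @param seed Seed mixed into every word hash.
#' @return A [feature_extractor()] with layers `bag` and `seq`.
#' @export
make_toy_extractor <- function(units = 64, seed = 1) {
  word_cache <- new.env(parent = emptyenv())
  text_cache <- new.env(parent = emptyenv())
  hash_vec <- function(token) {
    v <- word_cache[[token]]
    if (is.null(v)) {
      v <- with_preserved_rng({
        set.seed((string_hash(token) + seed * 7919L) %% 2147483647L)
        stats::rnorm(units)
      })
      word_cache[[token]] <- v
    }
    v
  }
  embed <- function(text) {
    hit <- text_cache[[text]]
    if (!is.null(hit)) return(hit)
    w <- split_words(text)
    if (length(w) == 0) stop_user("empty strings cannot be embedded")
    bag <- Reduce(`+`, lapply(w, hash_vec)) / length(w)
    bigrams <- paste(c("<s>", w[-length(w)]), w)
    wt <- seq_along(bigrams) / length(bigrams)
    seq_v <- Reduce(`+`, Map(function(b, x) hash_vec(b) * x, bigrams, wt)) /
      length(bigrams)
    out <- list(bag = bag, seq = seq_v)
    text_cache[[text]] <- out
    out
  }
  feature_extractor(layer_names = c("bag", "seq"),
                    units_per_layer = c(units, units),
                    embed = embed,
                    token_count = function(text) {
                      n <- length(split_words(text))
                      if (n == 0) stop_user("empty strings have no tokens")
                      n
                    })
}

#' Proposal-model contract
#'
#' A proposal model stands in for a masked language model: given a word
#' sequence with one designated mask position it returns a categorical
#' distribution over its vocabulary for the word at that position.
#'
#' @param vocabulary Character vector of candidate fill words.
#' @param propose `function(words, mask_pos)` returning a named non-negative
#'   numeric vector over `vocabulary` summing to 1.
#' @return Object of class `proposal_model`.
#' @export
proposal_model <- function(vocabulary, propose) {
  stopifnot(is.character(vocabulary), length(vocabulary) >= 1, is.function(propose))
  structure(list(vocabulary = vocabulary, propose = propose),
            class = "proposal_model")
}

check_proposal_dist <- function(p, vocabulary) {
  if (is.null(names(p)) || !setequal(names(p), vocabulary) ||
      any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop_user("proposal model returned an invalid categorical distribution")
  }
  p[vocabulary]
}

#' Fit a bigram proposal model to a corpus
#'
#' Counts word bigrams (with sentence-boundary markers) over all captions and
#' exposes masked-position fill distributions proportional to
#' P(word | left neighbour) * P(right neighbour | word) with add-k smoothing,
#' backing off to the unigram marginal when a neighbour is unknown or absent.
#' Supports the degenerate sequence consisting only of the unknown token.
#'
#' @param corpus A [caption_corpus()].
#' @param smoothing Add-k smoothing constant.
#' @return A [proposal_model()] over the corpus vocabulary.
#' @export
fit_toy_proposal <- function(corpus, smoothing = 0.05) {
  caps <- corpus_captions(corpus)$caption
  toks <- lapply(caps, split_words)
  vocab <- sort(unique(unlist(toks)))
  V <- length(vocab)
  ctx_levels <- c("<s>", vocab)
  nxt_levels <- c(vocab, "</s>")
  left <- matrix(0, length(ctx_levels), V, dimnames = list(ctx_levels, vocab))
  right <- matrix(0, V, length(nxt_levels), dimnames = list(vocab, nxt_levels))
  uni <- stats::setNames(numeric(V), vocab)
  for (tk in toks) {
    uni[tk] <- uni[tk] + 1
    prev <- c("<s>", tk); nxt <- c(tk, "</s>")
    for (i in seq_along(tk)) {
      left[prev[i], tk[i]] <- left[prev[i], tk[i]] + 1
      right[tk[i], nxt[i + 1]] <- right[tk[i], nxt[i + 1]] + 1
    }
  }
  p_left <- (left + smoothing) / (rowSums(left) + smoothing * V)
  p_right <- (right + smoothing) / (rowSums(right) + smoothing * ncol(right))
  p_uni <- (uni + smoothing) / (sum(uni) + smoothing * V)
  propose <- function(words, mask_pos) {
    stopifnot(mask_pos >= 1, mask_pos <= length(words))
    prev <- if (mask_pos > 1) words[mask_pos - 1] else "<s>"
    nxt <- if (mask_pos < length(words)) words[mask_pos + 1] else "</s>"
    p <- if (prev %in% rownames(p_left)) p_left[prev, ] else p_uni
    if (nxt %in% colnames(p_right)) p <- p * p_right[, nxt]
    if (sum(p) <= 0) p <- p_uni
    p / sum(p)
  }
  proposal_model(vocab, propose)
}

#' Linear forward model of brain responses
#'
#' Simulated voxel responses are a fixed linear mixing of the concatenated
#' layer features plus i.i.d. Gaussian noise, with run labels assigned
#' round-robin — enough structure for parameter-recovery tests, with no
#' claim to hemodynamic realism.
#'
#' @param n_units Total feature units (all layers concatenated).
#' @param n_voxels Number of voxels.
#' @param noise_sd Noise standard deviation (signal scale is O(1/sqrt(units))).
#' @param n_runs Number of runs.
#' @param seed Seed for the mixing matrix (and, offset, for the noise).
#' @return Object of class `linear_brain_model` holding the mixing matrix `W`.
#' @export
linear_brain_model <- function(n_units, n_voxels = 300, noise_sd = 0.1,
                               n_runs = 6, seed = 1) {
  W <- with_preserved_rng({
    set.seed(seed + 271L)
    matrix(stats::rnorm(n_units * n_voxels, sd = 1 / sqrt(n_units)),
           n_units, n_voxels)
  })
  structure(list(W = W, noise_sd = noise_sd, n_runs = n_runs, seed = seed),
            class = "linear_brain_model")
}

#' Brain-response container
#'
#' @param X Samples-by-voxels matrix of finite responses.
#' @param runs Run label per sample.
#' @param sample_ids Row ids.
#' @param regions Optional region label per voxel.
#' @return Object of class `brain_data`.
#' @export
brain_data <- function(X, runs, sample_ids = NULL, regions = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_user("brain responses must be finite")
  if (length(runs) != nrow(X)) stop_user("one run label per sample required")
  sample_ids <- sample_ids %||% rownames(X) %||% as.character(seq_len(nrow(X)))
  rownames(X) <- sample_ids
  structure(list(X = X, runs = as.character(runs), sample_ids = sample_ids,
                 regions = regions),
            class = "brain_data")
}

#' @export
print.brain_data <- function(x, ...) {
  cat(sprintf("<brain_data> %d samples x %d voxels, %d runs\n",
              nrow(x$X), ncol(x$X), length(unique(x$runs))))
  invisible(x)
}

#' Simulate brain responses from layer features
#'
#' @param features A [layer_features()] (layers are concatenated column-wise).
#' @param model A [linear_brain_model()].
#' @return A [brain_data()] with `model$n_runs` round-robin run labels.
#' @export
simulate_brain <- function(features, model) {
  stopifnot(inherits(features, "layer_features"),
            inherits(model, "linear_brain_model"))
  F <- do.call(cbind, features$layers)
  if (ncol(F) != nrow(model$W)) stop_user("feature width does not match mixing matrix")
  signal <- F %*% model$W
  noise <- with_preserved_rng({
    set.seed(model$seed + 997L)
    matrix(stats::rnorm(length(signal), sd = model$noise_sd),
           nrow(signal), ncol(signal))
  })
  runs <- sprintf("run%02d", ((seq_len(nrow(F)) - 1) %% model$n_runs) + 1)
  brain_data(signal + if (model$noise_sd > 0) noise else 0, runs = runs,
             sample_ids = features$sample_ids)
}
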