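# N-gram based caption-similarity metrics. No R package in the dependency
# stack provides these scorers, so they are implemented here following their
# standard published definitions (METEOR as the exact-match variant).

#' Tokenizer used by the surface metrics
#' @param x A string.
#' @return Lower-cased whitespace tokens.
#' @export
metric_tokenize <- function(x) split_words(tolower(x))

ngrams_of <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  vapply(seq_len(length(tokens) - n + 1),
         function(i) paste(tokens[i:(i + n - 1)], collapse = " "), character(1))
}

#' BLEU-4 with epsilon smoothing
#'
#' Modified n-gram precision (clip counts are maxima over references) with a
#' brevity penalty against the closest reference length. Orders for which the
#' hypothesis has no n-grams are dropped from the geometric mean; zero match
#' counts are smoothed by substituting `eps` matches.
#'
#' @param hypothesis Hypothesis string.
#' @param references Character vector of reference strings.
#' @param max_n Largest n-gram order (default 4).
#' @param eps Smoothing constant for zero match counts.
#' @param tokenizer Tokenizer function.
#' @return BLEU score in [0, 1].
#' @export
bleu_score <- function(hypothesis, references, max_n = 4, eps = 0.1,
                       tokenizer = metric_tokenize) {
  hyp <- tokenizer(hypothesis)
  refs <- lapply(references, tokenizer)
  if (length(hyp) == 0) return(0)
  logp <- numeric(0)
  for (n in seq_len(max_n)) {
    hg <- ngrams_of(hyp, n)
    if (length(hg) == 0) next
    hc <- table(hg)
    clip <- sapply(names(hc), function(g) {
      max(vapply(refs, function(r) sum(ngrams_of(r, n) == g), numeric(1)))
    })
    m <- sum(pmin(as.numeric(hc), clip))
    logp <- c(logp, log(max(m, eps) / length(hg)))
  }
  if (length(logp) == 0) return(0)
  c_len <- length(hyp)
  rl <- vapply(refs, length, numeric(1))
  r_len <- rl[order(abs(rl - c_len), rl)][1]
  bp <- if (c_len >= r_len) 1 else exp(1 - r_len / c_len)
  bp * exp(mean(logp))
}

#' ROUGE-L (longest common subsequence F-measure)
#'
#' @inheritParams bleu_score
#' @param beta Recall weight in the F-measure (1.2, the conventional value).
#' @return Highest ROUGE-L F-score over the references, in [0, 1].
#' @export
rouge_l_score <- function(hypothesis, references, beta = 1.2,
                          tokenizer = metric_tokenize) {
  hyp <- tokenizer(hypothesis)
  if (length(hyp) == 0) return(0)
  max(vapply(references, function(ref) {
    r <- tokenizer(ref)
    l <- lcs_length(hyp, r)
    if (l == 0) return(0)
    p <- l / length(hyp); rc <- l / length(r)
    (1 + beta^2) * p * rc / (rc + beta^2 * p)
  }, numeric(1)))
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb + 1)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1)
    for (j in seq_len(nb)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L else max(cur[j], prev[j + 1])
    }
    prev <- cur
  }
  prev[nb + 1]
}

#' Exact-match METEOR
#'
#' Unigram precision/recall harmonic mean weighted toward recall
#' (F = 10PR / (R + 9P)) with the fragmentation penalty
#' 0.5 * (chunks / matches)^3. Matching is exact-token only (no stemming or
#' synonyms); alignment is greedy left-to-right to the earliest unused
#' reference occurrence.
#'
#' @inheritParams bleu_score
#' @return Highest METEOR score over the references, in [0, 1].
#' @export
meteor_score <- function(hypothesis, references, tokenizer = metric_tokenize) {
  hyp <- tokenizer(hypothesis)
  if (length(hyp) == 0) return(0)
  max(vapply(references, function(ref) {
    r <- tokenizer(ref)
    used <- logical(length(r))
    map <- rep(NA_integer_, length(hyp))
    for (i in seq_along(hyp)) {
      j <- which(!used & r == hyp[i])
      if (length(j)) { map[i] <- j[1]; used[j[1]] <- TRUE }
    }
    m <- sum(!is.na(map))
    if (m == 0) return(0)
    p <- m / length(hyp); rc <- m / length(r)
    fmean <- 10 * p * rc / (rc + 9 * p)
    mm <- map[!is.na(map)]
    chunks <- 1 + sum(diff(mm) != 1 | diff(which(!is.na(map))) != 1)
    fmean * (1 - 0.5 * (chunks / m)^3)
  }, numeric(1)))
}

#' TF-IDF table for CIDEr
#'
#' Document frequencies are counted at the video level over the reference
#' corpus (an n-gram's document frequency is the number of videos whose
#' captions contain it).
#'
#' @param corpus A [caption_corpus()].
#' @param max_n Largest n-gram order.
#' @param tokenizer Tokenizer function.
#' @return List of class `cider_idf` with per-order document-frequency
#'   tables and the corpus size.
#' @export
build_cider_idf <- function(corpus, max_n = 4, tokenizer = metric_tokenize) {
  per_video <- lapply(corpus$entries, function(caps) {
    toks <- lapply(caps, tokenizer)
    lapply(seq_len(max_n), function(n) unique(unlist(lapply(toks, ngrams_of, n = n))))
  })
  df <- lapply(seq_len(max_n), function(n) {
    table(unlist(lapply(per_video, `[[`, n)))
  })
  structure(list(df = df, n_docs = length(corpus$entries), max_n = max_n),
            class = "cider_idf")
}

tfidf_vec <- function(tokens, n, idf) {
  g <- ngrams_of(tokens, n)
  if (length(g) == 0) return(numeric(0))
  tf <- table(g) / length(g)
  d <- as.numeric(idf$df[[n]][names(tf)])
  d[is.na(d)] <- 0
  w <- as.numeric(tf) * log(idf$n_docs / pmax(d, 1))
  stats::setNames(w, names(tf))
}

#' CIDEr score
#'
#' Average over n-gram orders (n <= 4) of the mean cosine similarity between
#' the TF-IDF n-gram vectors of the hypothesis and each reference, scaled by
#' 10 as is conventional.
#'
#' @inheritParams bleu_score
#' @param idf A `cider_idf` from [build_cider_idf()].
#' @return CIDEr score (0 to 10).
#' @export
cider_score <- function(hypothesis, references, idf,
                        tokenizer = metric_tokenize) {
  stopifnot(inherits(idf, "cider_idf"))
  hyp <- tokenizer(hypothesis)
  if (length(hyp) == 0) return(0)
  per_n <- vapply(seq_len(idf$max_n), function(n) {
    gh <- tfidf_vec(hyp, n, idf)
    mean(vapply(references, function(ref) {
      gr <- tfidf_vec(tokenizer(ref), n, idf)
      common <- intersect(names(gh), names(gr))
      num <- sum(gh[common] * gr[common])
      den <- sqrt(sum(gh^2)) * sqrt(sum(gr^2))
      if (den == 0) 0 else num / den
    }, numeric(1)))
  }, numeric(1))
  10 * mean(per_n)
}

#' Deterministic toy token-embedding provider
#'
#' Contextual token embeddings for BERTScore-style matching: each token's
#' vector mixes its own seeded-hash loading with those of its neighbours,
#' making embeddings context-dependent while remaining fully deterministic.
#'
#' @param units Embedding dimension.
#' @param seed Hash seed.
#' @param mix Neighbour mixing weight.
#' @return `function(tokens)` returning a tokens-by-units matrix.
#' @export
toy_embedding_provider <- function(units = 32, seed = 7, mix = 0.5) {
  cache <- new.env(parent = emptyenv())
  base_vec <- function(tok) {
    v <- cache[[tok]]
    if (is.null(v)) {
      v <- with_preserved_rng({
        set.seed((string_hash(tok) + seed * 104729L) %% 2147483647L)
        stats::rnorm(units)
      })
      cache[[tok]] <- v
    }
    v
  }
  function(tokens) {
    B <- do.call(rbind, lapply(tokens, base_vec))
    n <- nrow(B)
    ctx <- B
    if (n > 1) {
      prev <- rbind(0, B[-n, , drop = FALSE])
      nxt <- rbind(B[-1, , drop = FALSE], 0)
      ctx <- B + mix * (prev + nxt)
    }
    ctx / sqrt(rowSums(ctx^2))
  }
}

#' Token IDF weights from a reference corpus
#'
#' Inverse document frequency per token, counted at the video level:
#' idf(t) = log(N / df(t)) with N the number of videos. Tokens unseen in the
#' corpus receive the maximal weight log(N) (stored as the `default`
#' attribute), making rare hypothesis tokens count most in the IDF-weighted
#' precision variant.
#'
#' @param corpus A [caption_corpus()].
#' @param tokenizer Tokenizer function.
#' @return Named numeric vector of IDF weights with a `default` attribute.
#' @export
build_token_idf <- function(corpus, tokenizer = metric_tokenize) {
  per_video <- lapply(corpus$entries, function(caps) {
    unique(unlist(lapply(caps, tokenizer)))
  })
  df <- table(unlist(per_video))
  n <- length(corpus$entries)
  w <- log(n / as.numeric(df))
  structure(stats::setNames(w, names(df)), default = log(n))
}

#' BERTScore with a pluggable embedding provider
#'
#' Greedy cosine matching between contextual token embeddings: recall
#' averages each reference token's best match in the hypothesis, precision
#' averages each hypothesis token's best match in the reference, and F1 is
#' their harmonic mean. Optional IDF weights (named vector, tokens ->
#' weight) weight the token averages, giving the IDF-weighted precision
#' variant.
#'
#' @inheritParams bleu_score
#' @param provider Embedding provider (see [toy_embedding_provider()]).
#' @param idf_weights Optional named IDF weight vector.
#' @param aggregate `"mean"` (default, per-video averaging) or `"max"`.
#' @return Named vector with `p`, `r`, `f1` aggregated over references.
#' @export
bertscore <- function(hypothesis, references, provider,
                      idf_weights = NULL, aggregate = c("mean", "max"),
                      tokenizer = metric_tokenize) {
  aggregate <- match.arg(aggregate)
  hyp <- tokenizer(hypothesis)
  if (length(hyp) == 0) return(c(p = 0, r = 0, f1 = 0))
  Eh <- provider(hyp)
  wts <- function(tokens) {
    if (is.null(idf_weights)) return(rep(1, length(tokens)))
    w <- idf_weights[tokens]
    w[is.na(w)] <- attr(idf_weights, "default") %||% 1
    as.numeric(w)
  }
  wh <- wts(hyp)
  prf <- vapply(references, function(ref) {
    rt <- tokenizer(ref)
    Er <- provider(rt)
    S <- Eh %*% t(Er)
    p <- sum(apply(S, 1, max) * wh) / sum(wh)
    wr <- wts(rt)
    r <- sum(apply(S, 2, max) * wr) / sum(wr)
    c(p, r, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }, numeric(3))
  agg <- if (aggregate == "mean") rowMeans(prf) else apply(prf, 1, max)
  c(p = agg[[1]], r = agg[[2]], f1 = agg[[3]])
}

#' Layer-averaged feature correlation between two texts
#'
#' @param hypothesis,reference Strings.
#' @param extractor A [feature_extractor()].
#' @param stats Optional normalization stats applied to both sides.
#' @return Mean across-layer Pearson correlation.
#' @export
feature_correlation <- function(hypothesis, reference, extractor, stats = NULL) {
  h <- extractor$embed(hypothesis)
  r <- extractor$embed(reference)
  if (!is.null(stats)) {
    h <- apply_norm_vec(h, stats); r <- apply_norm_vec(r, stats)
  }
  mean(vapply(extractor$layer_names, function(ln) {
    v <- stats::cor(h[[ln]], r[[ln]])
    if (is.na(v)) 0 else v
  }, numeric(1)))
}

#' Metric configuration
#'
#' Bundles a metric with its per-video reference aggregation rule: scores
#' are averaged over a video's captions for feature correlation and
#' BERTScore, and the maximum is taken for BLEU, METEOR, ROUGE-L and CIDEr.
#' `metric` may also be a `function(hypothesis, reference)` for injected
#' scorers.
#'
#' @param metric Metric name (one of `feature_correlation`, `bleu4`,
#'   `meteor`, `rouge_l`, `cider`, `bertscore_p`, `bertscore_r`,
#'   `bertscore_f1`, `idf_weighted_p`) or a scoring function.
#' @param aggregate `"mean"` or `"max"`; defaults to the metric family's rule.
#' @param extractor Needed for `feature_correlation`.
#' @param provider Needed for the BERTScore family.
#' @param idf `cider_idf` for CIDEr, or named IDF weights for
#'   `idf_weighted_p`.
#' @param stats Optional normalization stats for feature correlation.
#' @param tokenizer Tokenizer for surface metrics.
#' @return List of class `metric_config`.
#' @export
metric_config <- function(metric, aggregate = NULL, extractor = NULL,
                          provider = NULL, idf = NULL, stats = NULL,
                          tokenizer = metric_tokenize) {
  known <- c("feature_correlation", "bleu4", "meteor", "rouge_l", "cider",
             "bertscore_p", "bertscore_r", "bertscore_f1", "idf_weighted_p")
  if (is.character(metric)) {
    metric <- match.arg(metric, known)
    if (is.null(aggregate)) {
      aggregate <- if (metric %in% c("feature_correlation", "bertscore_p",
                                     "bertscore_r", "bertscore_f1",
                                     "idf_weighted_p")) "mean" else "max"
    }
  } else {
    stopifnot(is.function(metric))
    aggregate <- aggregate %||% "mean"
  }
  structure(list(metric = metric, aggregate = aggregate, extractor = extractor,
                 provider = provider, idf = idf, stats = stats,
                 tokenizer = tokenizer), class = "metric_config")
}

score_one_ref <- function(hypothesis, reference, config) {
  m <- config$metric
  if (is.function(m)) return(m(hypothesis, reference))
  switch(m,
    feature_correlation = feature_correlation(hypothesis, reference,
                                              config$extractor, config$stats),
    bleu4 = bleu_score(hypothesis, reference, tokenizer = config$tokenizer),
    meteor = meteor_score(hypothesis, reference, tokenizer = config$tokenizer),
    rouge_l = rouge_l_score(hypothesis, reference, tokenizer = config$tokenizer),
    cider = cider_score(hypothesis, reference, config$idf,
                        tokenizer = config$tokenizer),
    bertscore_p = bertscore(hypothesis, reference, config$provider,
                            tokenizer = config$tokenizer)[["p"]],
    bertscore_r = bertscore(hypothesis, reference, config$provider,
                            tokenizer = config$tokenizer)[["r"]],
    bertscore_f1 = bertscore(hypothesis, reference, config$provider,
                             tokenizer = config$tokenizer)[["f1"]],
    idf_weighted_p = bertscore(hypothesis, reference, config$provider,
                               idf_weights = config$idf,
                               tokenizer = config$tokenizer)[["p"]])
}

#' Similarity between a description and a set of references
#'
#' Per-reference scores aggregated by the configured rule (mean or max). An
#' empty hypothesis returns the metric floor (0) with a warning.
#'
#' @param hypothesis Description string.
#' @param references Character vector of reference captions (>= 1).
#' @param config A [metric_config()].
#' @return Scalar score.
#' @export
similarity_score <- function(hypothesis, references, config) {
  stopifnot(inherits(config, "metric_config"))
  if (length(references) < 1) stop_user("need at least one reference")
  if (!nzchar(trimws(hypothesis))) {
    warning("empty hypothesis; returning metric floor value 0")
    return(0)
  }
  scores <- vapply(references, function(ref) score_one_ref(hypothesis, ref, config),
                   numeric(1), USE.NAMES = FALSE)
  if (config$aggregate == "mean") mean(scores) else max(scores)
}
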