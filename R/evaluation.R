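#' Cohen's d with pooled SD
#'
#' @param x,y Numeric vectors (e.g. per-sample correct and incorrect means).
#' @return Effect size (mean(x) - mean(y)) / pooled SD.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over the standard step-up procedure.
#' @param p Vector of p-values.
#' @return Adjusted p-values.
#' @export
fdr_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Percentile bootstrap confidence interval
#'
#' @param x Numeric vector.
#' @param conf Confidence level.
#' @param n_boot Bootstrap resamples.
#' @param statistic Function of a resample (default mean).
#' @return Named vector `lower`/`upper`.
#' @export
bootstrap_ci <- function(x, conf = 0.95, n_boot = 10000, statistic = mean) {
  stat <- vapply(seq_len(n_boot),
                 function(i) statistic(x[sample.int(length(x), replace = TRUE)]),
                 numeric(1))
  a <- (1 - conf) / 2
  stats::setNames(stats::quantile(stat, c(a, 1 - a), names = FALSE),
                  c("lower", "upper"))
}

# per-caption scores of a description against every caption of every video
per_video_scores <- function(description, corpus, config,
                             aggregate_within = NULL) {
  vapply(corpus$entries, function(caps) {
    sc <- vapply(caps, function(ref) score_one_ref(description, ref, config),
                 numeric(1), USE.NAMES = FALSE)
    switch(aggregate_within %||% config$aggregate,
           mean = mean(sc), max = max(sc))
  }, numeric(1))
}

#' Discriminability of a generated description
#'
#' The mean similarity of the description to the correct video's captions
#' minus its mean similarity to all incorrect videos' captions (scores
#' averaged within each set).
#'
#' @param description Generated description.
#' @param corpus A [caption_corpus()].
#' @param correct_id Video id of the correct video.
#' @param config A [metric_config()].
#' @return List of class `discriminability_result` with `correct_score`,
#'   `incorrect_score`, `difference`.
#' @export
discriminability <- function(description, corpus, correct_id, config) {
  if (!correct_id %in% names(corpus$entries)) stop_user("unknown video id: ", correct_id)
  score_caps <- function(caps) {
    mean(vapply(caps, function(ref) score_one_ref(description, ref, config),
                numeric(1), USE.NAMES = FALSE))
  }
  correct <- score_caps(corpus$entries[[correct_id]])
  other_caps <- unlist(corpus$entries[setdiff(names(corpus$entries), correct_id)],
                       use.names = FALSE)
  incorrect <- score_caps(other_caps)
  structure(list(correct_score = correct, incorrect_score = incorrect,
                 difference = correct - incorrect),
            class = "discriminability_result")
}

#' Effect size of discriminability across samples
#'
#' @param results List of `discriminability_result`s (one per sample).
#' @return Cohen's d between the correct and incorrect per-sample means.
#' @export
discriminability_d <- function(results) {
  cohens_d(vapply(results, `[[`, numeric(1), "correct_score"),
           vapply(results, `[[`, numeric(1), "incorrect_score"))
}

#' Number of incorrect reference captions for an identification analysis
#'
#' @param corpus A [caption_corpus()].
#' @param correct_id The correct video id.
#' @return Count of captions belonging to all other videos.
#' @export
n_incorrect_references <- function(corpus, correct_id) {
  sum(lengths(corpus$entries[setdiff(names(corpus$entries), correct_id)]))
}

#' Identification accuracy versus candidate-set size
#'
#' For each set size, the correct video must attain the highest per-video
#' similarity among itself and randomly drawn incorrect candidates (chance =
#' 1 / set size). Set size 2 enumerates all incorrect candidates
#' exhaustively; larger sets are resampled `repeats` times. Ties at the top
#' share credit equally.
#'
#' @param description Generated description.
#' @param corpus A [caption_corpus()].
#' @param correct_id Correct video id.
#' @param set_sizes Candidate-set sizes (2 to number of videos).
#' @param repeats Resamples per set size (> 2 candidates).
#' @param config A [metric_config()].
#' @param rescore_each_repeat Recompute scores on every repeat (needed for
#'   stochastic injected metrics; deterministic metrics are precomputed once).
#' @return List of class `identification_curve`: data.frame `curve` with
#'   `set_size`, `accuracy`, `chance`.
#' @export
identify_by_text <- function(description, corpus, correct_id,
                             set_sizes = c(2, 5, 10, 25, 50, 100),
                             repeats = 100, config,
                             rescore_each_repeat = FALSE) {
  ids <- names(corpus$entries)
  if (!correct_id %in% ids) stop_user("unknown video id: ", correct_id)
  incorrect <- setdiff(ids, correct_id)
  if (max(set_sizes) > length(ids)) stop_user("set size exceeds corpus size")
  score_of <- function(vid) {
    sc <- vapply(corpus$entries[[vid]],
                 function(ref) score_one_ref(description, ref, config),
                 numeric(1), USE.NAMES = FALSE)
    if (config$aggregate == "mean") mean(sc) else max(sc)
  }
  if (!rescore_each_repeat) {
    all_scores <- vapply(ids, score_of, numeric(1))
  }
  acc <- vapply(set_sizes, function(ss) {
    if (ss == 2 && !rescore_each_repeat) {
      sc <- all_scores[correct_id]
      oth <- all_scores[incorrect]
      return(mean(ifelse(sc > oth, 1, ifelse(sc == oth, 0.5, 0))))
    }
    wins <- vapply(seq_len(repeats), function(i) {
      sel <- sample(incorrect, ss - 1)
      if (rescore_each_repeat) {
        sc <- score_of(correct_id)
        oth <- vapply(sel, score_of, numeric(1))
      } else {
        sc <- all_scores[correct_id]
        oth <- all_scores[sel]
      }
      top <- max(c(sc, oth))
      if (sc == top) 1 / sum(c(sc, oth) == top) else 0
    }, numeric(1))
    mean(wins)
  }, numeric(1))
  structure(list(curve = data.frame(set_size = set_sizes, accuracy = acc,
                                    chance = 1 / set_sizes)),
            class = "identification_curve")
}

#' Pairwise feature-based video identification
#'
#' For each pair consisting of the correct candidate and one incorrect
#' candidate, the correct one wins if the decoded feature vector correlates
#' more strongly with its features; accuracy is the fraction of pairs won
#' (ties count half; chance = 0.5).
#'
#' @param decoded Numeric vector (decoded features of one sample), or a
#'   one-row [layer_features()] whose layers are concatenated.
#' @param candidates Matrix of candidate feature vectors (rows = videos), or
#'   [layer_features()].
#' @param correct_index Row of the correct candidate.
#' @return List with `accuracy` and `outcomes` (per-pair win indicator).
#' @export
identify_pairwise_by_features <- function(decoded, candidates, correct_index) {
  if (inherits(decoded, "layer_features")) {
    decoded <- as.vector(do.call(cbind, decoded$layers)[1, ])
  }
  if (inherits(candidates, "layer_features")) {
    candidates <- do.call(cbind, candidates$layers)
  }
  r <- row_cor(candidates, decoded)
  rc <- r[correct_index]
  ro <- r[-correct_index]
  outcomes <- ifelse(rc > ro, 1, ifelse(rc == ro, 0.5, 0))
  list(accuracy = mean(outcomes), outcomes = outcomes)
}

#' Generalizability angle between perception and imagery accuracy
#'
#' The angle (degrees) between the parity diagonal and the line from chance
#' (50%, 50%) to the observed accuracy pair:
#' angle = 45 - atan((imagery - 50) / (perception - 50)) * 180 / pi.
#' Smaller angles indicate stronger cross-state generalization. The standard
#' error is estimated by leave-one-pair-out jackknife when per-pair outcomes
#' are supplied.
#'
#' @param perception_acc,imagery_acc Accuracies in percent (perception > 50).
#' @param outcomes Optional matrix/data.frame with columns `perception` and
#'   `imagery` of per-pair outcomes (0/1), in percent units after averaging.
#' @return List of class `generalizability_result` with `angle_deg`,
#'   `perception`, `imagery` and `jackknife_se` (NA without outcomes).
#' @export
generalizability_angle <- function(perception_acc, imagery_acc,
                                   outcomes = NULL) {
  if (perception_acc <= 50) stop_user("perception accuracy must exceed chance (50)")
  ang <- function(p, i) 45 - atan((i - 50) / (p - 50)) * 180 / pi
  se <- NA_real_
  if (!is.null(outcomes)) {
    outcomes <- as.data.frame(outcomes)
    stopifnot(all(c("perception", "imagery") %in% names(outcomes)))
    n <- nrow(outcomes)
    loo <- vapply(seq_len(n), function(i) {
      ang(100 * mean(outcomes$perception[-i]), 100 * mean(outcomes$imagery[-i]))
    }, numeric(1))
    se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  }
  structure(list(angle_deg = ang(perception_acc, imagery_acc),
                 perception = perception_acc, imagery = imagery_acc,
                 jackknife_se = se),
            class = "generalizability_result")
}

# all distinct permutations of an index multiset (small n only)
multiset_perms <- function(items) {
  if (length(items) <= 1) return(list(items))
  out <- list()
  for (u in unique(items)) {
    rest <- items[-match(u, items)]
    out <- c(out, lapply(multiset_perms(rest), function(p) c(u, p)))
  }
  out
}

#' Word-order shuffled variants of a description
#'
#' Produces up to `max_variants` distinct word-order permutations of the
#' description (shuffling at the word level), excluding the original.
#' `mode = "nouns"` permutes only the positions the injected tagger marks as
#' nouns; descriptions with at most one noun yield an explicit skip.
#'
#' @param description Description string.
#' @param mode `"all"` or `"nouns"`.
#' @param max_variants Cap on returned variants (default 1000).
#' @param noun_tagger `function(words)` returning a logical noun mask
#'   (required for `mode = "nouns"`; a lexicon lookup suffices in tests).
#' @return Character vector of variants, or a list with `skipped = TRUE` and
#'   a `reason` when noun shuffling is not applicable.
#' @export
shuffle_words <- function(description, mode = c("all", "nouns"),
                          max_variants = 1000, noun_tagger = NULL) {
  mode <- match.arg(mode)
  words <- split_words(description)
  pos <- if (mode == "all") seq_along(words) else {
    if (is.null(noun_tagger)) stop_user("noun shuffling requires a noun_tagger")
    which(noun_tagger(words))
  }
  if (mode == "nouns" && length(pos) <= 1) {
    return(list(skipped = TRUE,
                reason = "at most one noun; noun-shuffling not applicable"))
  }
  toks <- words[pos]
  n_perm <- factorial(length(toks)) /
    prod(factorial(table(toks)))
  variants <- character(0)
  if (length(toks) <= 7) {
    perms <- multiset_perms(toks)
    variants <- vapply(perms, function(p) {
      w <- words; w[pos] <- p; paste(w, collapse = " ")
    }, character(1))
    variants <- setdiff(unique(variants), paste(words, collapse = " "))
    if (length(variants) > max_variants) {
      variants <- variants[sample.int(length(variants), max_variants)]
    }
  } else {
    seen <- new.env(parent = emptyenv())
    orig <- paste(words, collapse = " ")
    attempts <- 0
    while (length(variants) < min(max_variants, n_perm - 1) &&
           attempts < 30 * max_variants) {
      w <- words; w[pos] <- sample(toks)
      s <- paste(w, collapse = " ")
      attempts <- attempts + 1
      if (s != orig && is.null(seen[[s]])) {
        seen[[s]] <- TRUE
        variants <- c(variants, s)
      }
    }
  }
  variants
}

#' Pseudo-log-likelihood fluency score
#'
#' Sum over words of the log probability of the word given the sequence with
#' that whole word masked, under the proposal model — a masked-scoring
#' fluency proxy. Always <= 0; words outside the proposal vocabulary give
#' -Inf.
#'
#' @param description Description string.
#' @param proposal A [proposal_model()].
#' @param mask_token Mask placeholder.
#' @return Scalar pseudo-log-likelihood.
#' @export
pseudo_log_likelihood <- function(description, proposal,
                                  mask_token = "<MASK>") {
  words <- split_words(description)
  if (length(words) == 0) stop_user("empty description")
  sum(vapply(seq_along(words), function(i) {
    seq_w <- words; seq_w[i] <- mask_token
    p <- check_proposal_dist(proposal$propose(seq_w, i), proposal$vocabulary)
    pw <- if (words[i] %in% names(p)) p[[words[i]]] else 0
    log(pw)
  }, numeric(1)))
}

#' Impact of word-order shuffling on scores
#'
#' Scores the original description and each shuffled variant against the
#' references and (optionally) against target features, reports the rank of
#' the original by target feature correlation, the correlation distance
#' (1 - feature correlation) of each variant to the original, and flags the
#' most fluent (least disrupted) variant when a proposal model is supplied.
#'
#' @param description Original description.
#' @param shuffles Character vector of shuffled variants.
#' @param references Reference captions.
#' @param config A [metric_config()] for the reference scores.
#' @param extractor A [feature_extractor()] for feature correlations.
#' @param target Optional per-layer target vector list (or one-row
#'   [layer_features()]); defaults to the original's own features.
#' @param proposal Optional [proposal_model()] for fluency.
#' @param stats Optional normalization stats.
#' @return List of class `shuffle_evaluation` with a `table` data.frame
#'   (string, is_original, ref_score, target_r, corr_distance, fluency),
#'   `rank_of_original` and `most_fluent_variant`.
#' @export
shuffle_impact_report <- function(description, shuffles, references, config,
                                  extractor, target = NULL, proposal = NULL,
                                  stats = NULL) {
  all_strings <- c(description, shuffles)
  if (is.null(target)) {
    tv <- extractor$embed(description)
    if (!is.null(stats)) tv <- apply_norm_vec(tv, stats)
    target <- tv
  }
  scored <- score_candidates(all_strings, target, extractor, alpha = 0,
                             stats = stats)
  ref_scores <- vapply(all_strings, function(s) similarity_score(s, references, config),
                       numeric(1), USE.NAMES = FALSE)
  corr_dist <- vapply(all_strings, function(s) {
    1 - feature_correlation(s, description, extractor, stats)
  }, numeric(1), USE.NAMES = FALSE)
  fluency <- if (!is.null(proposal)) {
    vapply(all_strings, pseudo_log_likelihood, numeric(1), proposal = proposal,
           USE.NAMES = FALSE)
  } else rep(NA_real_, length(all_strings))
  tab <- data.frame(string = all_strings,
                    is_original = c(TRUE, rep(FALSE, length(shuffles))),
                    ref_score = ref_scores,
                    target_r = scored$r,
                    corr_distance = corr_dist,
                    fluency = fluency,
                    stringsAsFactors = FALSE)
  rank_orig <- rank(-tab$target_r, ties.method = "min")[1]
  most_fluent <- if (!is.null(proposal) && length(shuffles)) {
    shuffles[which.max(fluency[-1])]
  } else NA_character_
  structure(list(table = tab, rank_of_original = rank_orig,
                 most_fluent_variant = most_fluent),
            class = "shuffle_evaluation")
}

#' Self-BLEU diversity of grouped descriptions
#'
#' Each description is scored with multi-reference BLEU against the other
#' members of its group; the group's Self-BLEU is the mean. Higher values
#' mean less diverse descriptions.
#'
#' @param descriptions Character vector.
#' @param groups Group label per description (video or subject).
#' @param ... Passed to [bleu_score()].
#' @return Named numeric vector of per-group Self-BLEU values.
#' @export
self_bleu <- function(descriptions, groups, ...) {
  stopifnot(length(descriptions) == length(groups))
  vapply(split(descriptions, groups), function(d) {
    if (length(d) < 2) return(NA_real_)
    mean(vapply(seq_along(d), function(i) bleu_score(d[i], d[-i], ...),
                numeric(1)))
  }, numeric(1))
}
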