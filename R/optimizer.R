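#' Optimizer configuration
#'
#' Default settings: 100 iterations, 5 random
#' restarts, a beam of 5 candidates, 5 masked variants sampled per candidate,
#' 5 fills per masked variant, mask spans of up to 3 words, up to 2 extra
#' masking rounds, and a length-penalty exponent alpha = 0.1 — giving a
#' maximum per-step search width of
#' `beam_size * masked_per_candidate * fills_per_masked + beam_size` = 130.
#'
#' `penalty_form = "decay"` (default) scores candidates as s = r * l^(-alpha)
#' so the score decreases with token count for positive r, matching the
#' stated purpose of favouring concise descriptions; `"printed"` uses the
#' literal s = r * l^alpha form.
#'
#' @param iterations Optimization steps per restart.
#' @param restarts Independent restarts; the best final candidate wins.
#' @param beam_size Candidates retained after each step.
#' @param masked_per_candidate Masked variants sampled per beam candidate.
#' @param fills_per_masked Fill samples per masked variant.
#' @param max_span Longest word span replaceable by one mask.
#' @param max_extra_mask_rounds Additional masking rounds applied to freshly
#'   masked variants (total masks per variant <= 1 + this).
#' @param alpha Length-penalty exponent (>= 0).
#' @param seed Seed controlling all optimizer randomness.
#' @param init_token Noninformative initial description.
#' @param penalty_form `"decay"` or `"printed"` (see above).
#' @param mask_token Mask placeholder.
#' @param stop_r Optional convergence threshold: the search stops early once
#'   the best layer-averaged correlation reaches this value — the remaining
#'   iterations of the restart, and any remaining restarts, are skipped
#'   (`NULL`, the default, runs the full budget).
#' @return List of class `optimizer_config`.
#' @export
optimizer_config <- function(iterations = 100, restarts = 5, beam_size = 5,
                             masked_per_candidate = 5, fills_per_masked = 5,
                             max_span = 3, max_extra_mask_rounds = 2,
                             alpha = 0.1, seed = 1, init_token = "<unk>",
                             penalty_form = c("decay", "printed"),
                             mask_token = "<MASK>", stop_r = NULL) {
  penalty_form <- match.arg(penalty_form)
  stopifnot(iterations >= 0, restarts >= 1, beam_size >= 1,
            masked_per_candidate >= 1, fills_per_masked >= 1, max_span >= 1,
            max_extra_mask_rounds >= 0, alpha >= 0)
  structure(as.list(environment()), class = "optimizer_config")
}

#' Search-width bound implied by a configuration
#' @param config An [optimizer_config()].
#' @return Maximum number of candidates scored in one step.
#' @export
search_width_bound <- function(config) {
  config$beam_size * config$masked_per_candidate * config$fills_per_masked +
    config$beam_size
}

# One masking round over a single-space-joined candidate string: replace each
# mask-free span of up to max_span words with one mask, and interpolate a mask
# at every gap. Works by substring surgery on precomputed word boundaries so
# the whole round is a few vectorized paste0 calls.
mask_round <- function(str, max_span, mask_token) {
  words <- strsplit(str, " ", fixed = TRUE)[[1]]
  n <- length(words)
  lens <- nchar(words)
  ends <- cumsum(lens + 1L) - 1L    # char index of each word's last char
  starts <- ends - lens + 1L
  cm <- c(0L, cumsum(words == mask_token))
  span_i <- integer(0); span_j <- integer(0)
  for (s in seq_len(min(max_span, n))) {
    i <- seq_len(n - s + 1L)
    j <- i + s - 1L
    ok <- (cm[j + 1L] - cm[i]) == 0L  # span contains no mask
    span_i <- c(span_i, i[ok]); span_j <- c(span_j, j[ok])
  }
  g <- 0:n
  e_prev <- c(0L, ends)               # prefix ends (0 -> empty prefix)
  s_next <- c(starts, nchar(str) + 2L)  # suffix starts (past end -> empty)
  pre <- substring(str, 1L, c(e_prev[span_i], e_prev[g + 1L]))
  suf <- substring(str, c(s_next[span_j + 1L], s_next[g + 1L]), nchar(str))
  sep1 <- character(length(pre)); sep1[nzchar(pre)] <- " "
  sep2 <- character(length(suf)); sep2[nzchar(suf)] <- " "
  unique(paste0(pre, sep1, mask_token, sep2, suf))
}

.variant_cache <- new.env(parent = emptyenv())

#' Enumerate masked variants of a candidate description
#'
#' Produces the exhaustive, duplicate-free list of masked sequences obtained
#' by replacing each word span (up to `max_span` words) with a single mask
#' token or interpolating a mask between words or at either end — e.g.
#' "metal shapes" yields "<MASK> shapes", "metal <MASK>", "<MASK>",
#' "metal <MASK> shapes", "<MASK> metal shapes" and "metal shapes <MASK>".
#' The same procedure is re-applied to freshly masked variants up to
#' `max_extra_mask_rounds` times, yielding multi-mask variants such as
#' "<MASK> <MASK> shapes"; every variant carries between 1 and
#' `1 + max_extra_mask_rounds` masks.
#'
#' @param candidate Candidate description string (non-empty).
#' @param max_span Longest replaceable word span.
#' @param max_extra_mask_rounds Extra masking rounds.
#' @param mask_token Mask placeholder.
#' @return Character vector of masked variants.
#' @export
enumerate_masked_variants <- function(candidate, max_span = 3,
                                      max_extra_mask_rounds = 2,
                                      mask_token = "<MASK>") {
  words <- split_words(candidate)
  if (length(words) == 0) stop_user("candidate must be non-empty")
  key <- paste(max_span, max_extra_mask_rounds, mask_token, candidate, sep = "\r")
  hit <- .variant_cache[[key]]
  if (!is.null(hit)) return(hit)
  all_v <- frontier <- mask_round(paste(words, collapse = " "), max_span,
                                  mask_token)
  for (round in seq_len(max_extra_mask_rounds)) {
    nxt <- unique(unlist(lapply(frontier, mask_round, max_span = max_span,
                                mask_token = mask_token), use.names = FALSE))
    frontier <- setdiff(nxt, all_v)
    if (length(frontier) == 0) break
    all_v <- c(all_v, frontier)
  }
  # bounded memoization: drop the cache when it grows too large
  n_cached <- .variant_cache[[".count"]] %||% 0L
  if (n_cached > 2000L) {
    rm(list = ls(.variant_cache, all.names = TRUE), envir = .variant_cache)
    n_cached <- 0L
  }
  if (length(all_v) <= 4000L) {
    .variant_cache[[key]] <- all_v
    .variant_cache[[".count"]] <- n_cached + 1L
  }
  all_v
}

#' Sample masked variants for the unmasking stage
#'
#' Uniform sample without replacement; when fewer variants exist than
#' requested, all are returned. Draws come from the current RNG stream so a
#' fixed seed reproduces the subset.
#'
#' @param variants Character vector of masked variants.
#' @param n Number to select.
#' @return Character vector of selected variants.
#' @export
sample_masked_candidates <- function(variants, n = 5) {
  if (length(variants) <= n) return(variants)
  variants[sample.int(length(variants), n)]
}

#' Fill masks with proposal-model samples
#'
#' Masks are resolved left to right, each fill conditioning on previously
#' filled words. For the first mask, up to `fills` distinct words are drawn
#' without replacement from the proposal distribution, branching into that
#' many candidates; remaining masks take one sampled word per branch.
#' Duplicate filled strings are removed.
#'
#' @param masked Masked sequence string (>= 1 mask).
#' @param proposal A [proposal_model()].
#' @param fills Number of fill samples.
#' @param mask_token Mask placeholder.
#' @return Character vector of filled candidate strings.
#' @export
fill_masks <- function(masked, proposal, fills = 5, mask_token = "<MASK>") {
  stopifnot(inherits(proposal, "proposal_model"))
  words <- split_words(masked)
  pos <- which(words == mask_token)
  if (length(pos) == 0) stop_user("no mask present in: ", masked)
  p1 <- check_proposal_dist(proposal$propose(words, pos[1]), proposal$vocabulary)
  support <- sum(p1 > 0)
  k <- min(fills, support)
  first <- sample(proposal$vocabulary, k, prob = p1)
  out <- vapply(first, function(w1) {
    seq_w <- words
    seq_w[pos[1]] <- w1
    for (p in pos[-1]) {
      pp <- check_proposal_dist(proposal$propose(seq_w, p), proposal$vocabulary)
      seq_w[p] <- sample(proposal$vocabulary, 1, prob = pp)
    }
    paste(seq_w, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  unique(out)
}

#' Score candidate descriptions against target features
#'
#' For each candidate, r is the across-unit Pearson correlation between the
#' candidate's features and the target features, averaged over layers; a
#' layer where the candidate's feature vector has zero variance contributes
#' 0. The ranked score applies the length penalty:
#' s = r * l^(-alpha) (`"decay"`, default) or s = r * l^alpha (`"printed"`),
#' with l the candidate's token count.
#'
#' @param candidates Character vector of candidate strings.
#' @param target Named list of per-layer target vectors (or a one-row
#'   [layer_features()]).
#' @param extractor A [feature_extractor()].
#' @param alpha Length-penalty exponent.
#' @param stats Optional `feature_norm_stats` applied to candidate features
#'   (use the stats the decoders were trained with when the target lives in
#'   normalized space).
#' @param penalty_form `"decay"` or `"printed"`.
#' @return data.frame with columns `candidate`, `r`, `l`, `s`, sorted as
#'   supplied.
#' @export
score_candidates <- function(candidates, target, extractor, alpha = 0.1,
                             stats = NULL,
                             penalty_form = c("decay", "printed")) {
  penalty_form <- match.arg(penalty_form)
  if (inherits(target, "layer_features")) {
    stopifnot(length(target$sample_ids) == 1)
    target <- lapply(target$layers, function(m) as.vector(m[1, ]))
  }
  stopifnot(setequal(names(target), extractor$layer_names))
  feats <- lapply(candidates, function(s) {
    v <- extractor$embed(s)
    if (!is.null(stats)) v <- apply_norm_vec(v, stats)
    v
  })
  r_layers <- vapply(extractor$layer_names, function(ln) {
    M <- do.call(rbind, lapply(feats, `[[`, ln))
    r <- row_cor(M, target[[ln]])
    r[is.na(r)] <- 0  # zero-variance candidate vector in this layer
    r
  }, numeric(length(candidates)))
  if (length(candidates) == 1) r_layers <- matrix(r_layers, nrow = 1)
  r <- rowMeans(r_layers)
  l <- vapply(candidates, extractor$token_count, numeric(1), USE.NAMES = FALSE)
  s <- if (penalty_form == "decay") r * l^(-alpha) else r * l^alpha
  data.frame(candidate = candidates, r = r, l = l, s = s,
             stringsAsFactors = FALSE)
}

#' Evolve a description aligned with target features
#'
#' The core loop: starting from a noninformative token, each step (i) masks
#' every beam candidate by word replacement and interpolation, (ii) unmasks
#' sampled variants with proposal-model draws, and (iii) scores all new and
#' original candidates by length-penalized layer-averaged feature
#' correlation, retaining the top beam. The process repeats for
#' `config$iterations` steps and `config$restarts` restarts; the candidate
#' with the highest penalized score across restarts wins. Because original
#' beam candidates are always rescored into the pool, the best score per
#' restart is non-decreasing over iterations.
#'
#' @param target Named per-layer target vector list or one-row
#'   [layer_features()].
#' @param extractor A [feature_extractor()].
#' @param proposal A [proposal_model()].
#' @param config An [optimizer_config()].
#' @param stats Optional normalization stats for candidate features.
#' @return List with `description` (winner), `score` (its scored row),
#'   `restart` (winning restart), and `trace` (data.frame: restart, iter,
#'   best candidate, r, l, s, pool_size).
#' @export
optimize_description <- function(target, extractor, proposal,
                                 config = optimizer_config(), stats = NULL) {
  stopifnot(inherits(config, "optimizer_config"))
  set.seed(config$seed)
  trace <- vector("list", config$restarts)
  finals <- vector("list", config$restarts)
  for (rs in seq_len(config$restarts)) {
    beam <- score_candidates(config$init_token, target, extractor,
                             config$alpha, stats, config$penalty_form)
    rows <- vector("list", config$iterations)
    it_done <- 0
    for (it in seq_len(config$iterations)) {
      new_cands <- unlist(lapply(beam$candidate, function(cand) {
        variants <- enumerate_masked_variants(cand, config$max_span,
                                              config$max_extra_mask_rounds,
                                              config$mask_token)
        sel <- sample_masked_candidates(variants, config$masked_per_candidate)
        unlist(lapply(sel, fill_masks, proposal = proposal,
                      fills = config$fills_per_masked,
                      mask_token = config$mask_token), use.names = FALSE)
      }), use.names = FALSE)
      pool <- unique(c(beam$candidate, new_cands))
      scored <- score_candidates(pool, target, extractor, config$alpha,
                                 stats, config$penalty_form)
      ord <- order(-scored$s, scored$l, scored$candidate)
      beam <- scored[ord[seq_len(min(config$beam_size, nrow(scored)))], ]
      rows[[it]] <- data.frame(restart = rs, iter = it,
                               best = beam$candidate[1], r = beam$r[1],
                               l = beam$l[1], s = beam$s[1],
                               pool_size = length(pool),
                               stringsAsFactors = FALSE)
      it_done <- it
      if (!is.null(config$stop_r) && beam$r[1] >= config$stop_r) break
    }
    trace[[rs]] <- do.call(rbind, rows[seq_len(it_done)])
    finals[[rs]] <- beam[1, ]
    if (!is.null(config$stop_r) && beam$r[1] >= config$stop_r) break
  }
  finals <- finals[!vapply(finals, is.null, logical(1))]
  fin <- do.call(rbind, finals)
  win <- order(-fin$s, fin$l, fin$candidate)[1]
  list(description = fin$candidate[win], score = fin[win, ],
       restart = win,
       trace = do.call(rbind, trace[!vapply(trace, is.null, logical(1))]))
}

#' Write an optimization trace as JSON lines
#'
#' @param result Result of [optimize_description()].
#' @param path Output path (one JSON record per iteration per restart).
#' @export
write_trace_jsonl <- function(result, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  tr <- result$trace
  for (i in seq_len(nrow(tr))) {
    writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE), con)
  }
  invisible(path)
}
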