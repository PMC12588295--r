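#' Feature-extractor contract
#'
#' A feature extractor turns a text string into one embedding vector per
#' layer, emulating token-averaged layerwise embeddings from a language
#' model (special tokens excluded from both the average and the token count).
#' The package treats the extractor as a contract so that any deterministic
#' implementation — the built-in toy extractor of [make_toy_extractor()] or an
#' adapter around a real language model — can drive decoding, optimization
#' and evaluation.
#'
#' @param layer_names Ordered character vector of layer names.
#' @param units_per_layer Integer vector, units per layer (same order).
#' @param embed `function(text)` returning a named list of numeric vectors,
#'   one per layer, all finite.
#' @param token_count `function(text)` returning a positive integer for
#'   non-empty text (special tokens excluded).
#' @param tokenize Optional `function(text)` returning the word tokens.
#' @return An object of class `feature_extractor`.
#' @export
feature_extractor <- function(layer_names, units_per_layer, embed, token_count,
                              tokenize = NULL) {
  stopifnot(is.character(layer_names), length(layer_names) >= 1,
            length(units_per_layer) == length(layer_names),
            all(units_per_layer >= 1),
            is.function(embed), is.function(token_count))
  structure(list(layer_names = layer_names,
                 units_per_layer = stats::setNames(as.integer(units_per_layer),
                                                   layer_names),
                 embed = embed, token_count = token_count,
                 tokenize = tokenize %||% split_words),
            class = "feature_extractor")
}

#' Layerwise feature container
#'
#' Holds one samples-by-units matrix per layer with sample ids aligned across
#' layers; the lingua franca between text and brain throughout the package.
#'
#' @param layers Named list of numeric matrices (same row count everywhere).
#' @param sample_ids Character vector of row ids.
#' @return An object of class `layer_features`.
#' @export
layer_features <- function(layers, sample_ids = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  layers <- lapply(layers, function(m) {
    m <- as.matrix(m)
    if (!all(is.finite(m))) stop_user("layer features must be finite")
    m
  })
  n <- unique(vapply(layers, nrow, integer(1)))
  if (length(n) != 1) stop_user("all layers must have the same sample count")
  if (is.null(sample_ids)) sample_ids <- rownames(layers[[1]]) %||% as.character(seq_len(n))
  if (length(sample_ids) != n) stop_user("sample_ids length mismatch")
  layers <- lapply(layers, function(m) { rownames(m) <- sample_ids; m })
  structure(list(layers = layers, sample_ids = sample_ids),
            class = "layer_features")
}

#' @export
print.layer_features <- function(x, ...) {
  cat(sprintf("<layer_features> %d samples; layers: %s\n", length(x$sample_ids),
              paste(sprintf("%s[%d]", names(x$layers),
                            vapply(x$layers, ncol, integer(1))), collapse = ", ")))
  invisible(x)
}

#' @rdname layer_features
#' @param x A `layer_features` object.
#' @param i Row index/ids.
#' @export
lf_rows <- function(x, i) {
  layer_features(lapply(x$layers, function(m) m[i, , drop = FALSE]),
                 sample_ids = x$sample_ids[if (is.character(i)) match(i, x$sample_ids) else i])
}

#' Compute layerwise features for a set of texts
#'
#' Applies the extractor to each text and stacks the per-layer vectors into
#' one matrix per layer (one row per text). Extraction is deterministic:
#' the same text always yields identical rows.
#'
#' @param extractor A [feature_extractor()].
#' @param texts Character vector of non-empty strings.
#' @param ids Optional row ids (default `seq_along(texts)`).
#' @return A [layer_features()] with one row per text.
#' @export
extract_text_features <- function(extractor, texts, ids = NULL) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (length(texts) == 0) stop_user("no texts supplied")
  if (any(!nzchar(trimws(texts)))) stop_user("empty strings cannot be embedded")
  per_text <- lapply(texts, function(tx) {
    v <- extractor$embed(tx)
    if (!identical(names(v), extractor$layer_names) ||
        !all(lengths(v) == extractor$units_per_layer)) {
      stop_user("extractor output violates the layer/unit contract")
    }
    v
  })
  layers <- lapply(stats::setNames(extractor$layer_names, extractor$layer_names),
                   function(ln) do.call(rbind, lapply(per_text, `[[`, ln)))
  layer_features(layers, sample_ids = ids %||% as.character(seq_along(texts)))
}

#' Average caption-level features per video
#'
#' Each video's feature row is the arithmetic mean of its captions' rows,
#' mirroring per-video averaging over multiple annotated captions.
#'
#' @param caption_features [layer_features()], one row per caption.
#' @param grouping Character vector of video ids, one per caption row.
#' @param allowed Optional vector of valid video ids; any id outside it errors.
#' @return [layer_features()] with one row per video (order of first
#'   appearance in `grouping`).
#' @export
aggregate_video_features <- function(caption_features, grouping, allowed = NULL) {
  stopifnot(inherits(caption_features, "layer_features"))
  n <- length(caption_features$sample_ids)
  if (length(grouping) != n) stop_user("grouping must label every caption row")
  if (any(is.na(grouping) | !nzchar(grouping))) stop_user("grouping ids must be non-empty")
  if (!is.null(allowed) && !all(grouping %in% allowed)) {
    stop_user("unknown video id in grouping: ",
              paste(unique(setdiff(grouping, allowed)), collapse = ", "))
  }
  f <- factor(grouping, levels = unique(grouping))
  layers <- lapply(caption_features$layers, function(m) {
    agg <- rowsum(m, f) / as.vector(table(f))
    agg
  })
  layer_features(layers, sample_ids = levels(f))
}

#' Z-score normalization of layer features
#'
#' Per-unit means and SDs are estimated from a designated training subset and
#' applied unchanged to any other data, as when decoders are trained and
#' evaluated in a normalized feature space. Units whose training SD falls
#' below `epsilon` are flagged and mapped to zero rather than raising an
#' error.
#'
#' @param features [layer_features()] to transform.
#' @param stats A `feature_norm_stats` object from a previous fit, or `NULL`
#'   to fit new statistics.
#' @param fit_rows Row indices (or ids) used for fitting when `stats` is
#'   `NULL`; defaults to all rows. Must contain at least 2 samples.
#' @param epsilon Threshold below which a unit's SD is treated as zero.
#' @return List with elements `features` (transformed [layer_features()]) and
#'   `stats` (`feature_norm_stats`: per layer `mean`, `sd`, logical `flag`,
#'   plus the `epsilon` and fit provenance).
#' @export
normalize_features <- function(features, stats = NULL, fit_rows = NULL,
                               epsilon = 1e-8) {
  stopifnot(inherits(features, "layer_features"))
  if (is.null(stats)) {
    idx <- fit_rows %||% seq_along(features$sample_ids)
    if (is.character(idx)) idx <- match(idx, features$sample_ids)
    if (length(idx) < 2) stop_user("need >= 2 samples to fit normalization stats")
    stats <- structure(list(
      layers = lapply(features$layers, function(m) {
        mu <- colMeans(m[idx, , drop = FALSE])
        sdv <- apply(m[idx, , drop = FALSE], 2, stats::sd)
        list(mean = mu, sd = sdv, flag = sdv < epsilon)
      }),
      epsilon = epsilon,
      fitted_from = features$sample_ids[idx]),
      class = "feature_norm_stats")
  }
  out <- Map(function(m, st) {
    z <- sweep(sweep(m, 2, st$mean), 2, ifelse(st$flag, 1, st$sd), "/")
    z[, st$flag] <- 0
    z
  }, features$layers, stats$layers[names(features$layers)])
  list(features = layer_features(out, sample_ids = features$sample_ids),
       stats = stats)
}

#' Apply stored normalization stats to a single per-layer vector list
#' @keywords internal
apply_norm_vec <- function(vecs, stats) {
  Map(function(v, st) {
    z <- (v - st$mean) / ifelse(st$flag, 1, st$sd)
    z[st$flag] <- 0
    z
  }, vecs, stats$layers[names(vecs)])
}
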