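#' Caption database for search-based prediction
#'
#' Pairs caption strings with their precomputed layer features (computed with
#' the same extractor and normalization as the decoding targets).
#'
#' @param captions Character vector.
#' @param features [layer_features()] with one row per caption.
#' @param provenance Optional label vector.
#' @return Object of class `caption_database`.
#' @export
caption_database <- function(captions, features, provenance = NULL) {
  stopifnot(inherits(features, "layer_features"))
  if (length(captions) == 0) stop_user("empty caption database")
  if (length(captions) != length(features$sample_ids)) {
    stop_user("captions and feature rows must align")
  }
  structure(list(captions = captions, features = features,
                 provenance = provenance), class = "caption_database")
}

#' Database-search description prediction
#'
#' The baseline that searches a caption database for the entry whose
#' features have the highest mean across-layer Pearson correlation with the
#' target features; ties break deterministically by database order.
#'
#' @param target Per-layer target vector list or one-row [layer_features()].
#' @param db A [caption_database()].
#' @return List with `caption`, `index` and `r` (its layer-averaged
#'   correlation), plus `scores` for all entries.
#' @export
db_search_predict <- function(target, db) {
  stopifnot(inherits(db, "caption_database"))
  if (inherits(target, "layer_features")) {
    stopifnot(length(target$sample_ids) == 1)
    target <- lapply(target$layers, function(m) as.vector(m[1, ]))
  }
  r_layers <- vapply(names(db$features$layers), function(ln) {
    r <- row_cor(db$features$layers[[ln]], target[[ln]])
    r[is.na(r)] <- 0
    r
  }, numeric(length(db$captions)))
  if (length(db$captions) == 1) r_layers <- matrix(r_layers, nrow = 1)
  scores <- as.vector(rowMeans(r_layers))
  idx <- unname(which.max(scores))  # first maximum = database order tie-break
  list(caption = db$captions[idx], index = idx, r = scores[idx],
       scores = scores)
}

#' Uniform (untrained) proposal-model control
#'
#' Suggests every vocabulary word with equal probability regardless of
#' context — the genetic-algorithm-like control against which the fitted
#' proposal model is compared.
#'
#' @param vocabulary Character vector.
#' @return A [proposal_model()].
#' @export
uniform_proposal_model <- function(vocabulary) {
  p <- stats::setNames(rep(1 / length(vocabulary), length(vocabulary)),
                       vocabulary)
  proposal_model(vocabulary, function(words, mask_pos) p)
}
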