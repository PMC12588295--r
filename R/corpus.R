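#' Caption corpus
#'
#' A corpus maps video ids to one or more reference caption strings and labels
#' each video as belonging to the training or test split. Every analysis in
#' the package that compares generated descriptions with references consumes
#' this container.
#'
#' @param entries Named list: video id -> character vector of captions.
#' @param split Named character vector (`"train"` or `"test"`) with one entry
#'   per video id. Defaults to all `"train"`.
#' @return An object of class `caption_corpus`.
#' @export
caption_corpus <- function(entries, split = NULL) {
  if (length(entries) == 0) stop_user("corpus must contain at least one video")
  ids <- names(entries)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop_user("video ids must be unique non-empty names")
  }
  ok <- vapply(entries, function(x) {
    is.character(x) && length(x) >= 1 && all(nzchar(trimws(x)))
  }, logical(1))
  if (!all(ok)) {
    stop_user("every video needs >= 1 non-empty caption; offending ids: ",
              paste(ids[!ok], collapse = ", "))
  }
  if (is.null(split)) split <- stats::setNames(rep("train", length(ids)), ids)
  if (!setequal(names(split), ids) || !all(split %in% c("train", "test"))) {
    stop_user("split labels must cover exactly the video ids with train/test values")
  }
  structure(list(entries = entries, split = split[ids]), class = "caption_corpus")
}

#' @export
print.caption_corpus <- function(x, ...) {
  n <- length(x$entries)
  cat(sprintf("<caption_corpus> %d videos (%d train / %d test), %d captions\n",
              n, sum(x$split == "train"), sum(x$split == "test"),
              sum(lengths(x$entries))))
  invisible(x)
}

#' @rdname caption_corpus
#' @param corpus A `caption_corpus`.
#' @param which `"train"`, `"test"` or `"all"`.
#' @export
corpus_ids <- function(corpus, which = c("all", "train", "test")) {
  which <- match.arg(which)
  ids <- names(corpus$entries)
  if (which == "all") ids else ids[corpus$split == which]
}

#' Flatten a corpus into a caption table
#'
#' @param corpus A `caption_corpus`.
#' @return data.frame with columns `video_id`, `caption`.
#' @export
corpus_captions <- function(corpus) {
  data.frame(video_id = rep(names(corpus$entries), lengths(corpus$entries)),
             caption = unlist(corpus$entries, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Read / write caption corpora
#'
#' TSV files hold one `video_id<TAB>caption` pair per line (no header by
#' default when writing via [write_captions_tsv()] a header line is included);
#' JSON files map ids to arrays of captions with an optional parallel `split`
#' map.
#'
#' @param path File path.
#' @param split Optional named split vector (see [caption_corpus()]).
#' @return A `caption_corpus`.
#' @export
read_captions_tsv <- function(path, split = NULL) {
  if (!file.exists(path)) stop_user("caption file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("video_id", "caption") %in% names(dt))) {
    stop_user("caption TSV needs columns video_id and caption: ", path)
  }
  entries <- split(dt$caption, factor(dt$video_id, levels = unique(dt$video_id)))
  caption_corpus(as.list(entries), split = split)
}

#' @rdname read_captions_tsv
#' @param corpus A `caption_corpus`.
#' @export
write_captions_tsv <- function(corpus, path) {
  data.table::fwrite(corpus_captions(corpus), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname read_captions_tsv
#' @export
read_captions_json <- function(path) {
  if (!file.exists(path)) stop_user("caption file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$entries)) {
    caption_corpus(as.list(obj$entries), split = unlist(obj$split))
  } else {
    caption_corpus(as.list(obj))
  }
}

#' @rdname read_captions_tsv
#' @export
write_captions_json <- function(corpus, path) {
  jsonlite::write_json(list(entries = corpus$entries,
                            split = as.list(corpus$split)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
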