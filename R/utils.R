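# Internal helpers shared across modules.

# Run code with the global RNG state saved and restored afterwards, so
# deterministic hashing (seeded draws per token) never disturbs a caller's
# random stream.
with_preserved_rng <- function(code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(code)
}

# Deterministic 31-bit polynomial rolling hash of a string (UTF-8 code points).
string_hash <- function(x) {
  ints <- utf8ToInt(x)
  h <- 0
  for (i in ints) h <- (h * 131 + i) %% 2147483647
  as.integer(h)
}

# Pearson correlation of every row of M against vector v; constant rows (or a
# constant v) yield NA. The vector is centered with the same single-pass
# mean used by rowMeans so that a row identical to v correlates at exactly 1.
row_cor <- function(M, v) {
  M <- as.matrix(M)
  Mc <- M - rowMeans(M)
  vc <- v - sum(v) / length(v)
  # numerator and norms share rowSums' accumulation so that a row identical
  # to v yields r == 1 exactly
  num <- rowSums(Mc * rep(vc, each = nrow(Mc)))
  denom <- unname(sqrt(rowSums(Mc * Mc) * sum(vc * vc)))
  r <- unname(num) / denom
  r[!is.finite(r)] <- NA_real_
  r
}

# Column-wise Pearson correlation between two aligned matrices.
col_cor <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  r <- colSums(Ac * Bc) / sqrt(colSums(Ac * Ac) * colSums(Bc * Bc))
  r[!is.finite(r)] <- NA_real_
  r
}

split_words <- function(x) {
  w <- strsplit(x, " ", fixed = TRUE)[[1]]
  w <- w[nzchar(w)]
  if (length(w) && any(grepl("[[:space:]]", w))) {
    w <- unlist(strsplit(w, "[[:space:]]+"))
    w <- w[nzchar(w)]
  }
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_user <- function(...) {
  stop(structure(class = c("neurocaption_user_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
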