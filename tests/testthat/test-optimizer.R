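test_that("masked-variant enumeration covers replacements and interpolations", {
  v1 <- enumerate_masked_variants("metal shapes", max_extra_mask_rounds = 0)
  expect_setequal(v1, c("<MASK> shapes", "metal <MASK>", "<MASK>",
                        "metal <MASK> shapes", "<MASK> metal shapes",
                        "metal shapes <MASK>"))
  expect_length(v1, 6)  # 3 replacements + 3 interpolations for 2 words
  v <- enumerate_masked_variants("metal shapes")
  expect_true(all(c("<MASK> <MASK> shapes", "metal <MASK> <MASK>") %in% v))
  expect_true(all(vapply(strsplit(v, " "),
                         function(w) sum(w == "<MASK>"), numeric(1)) <= 3))
  expect_true(all(vapply(strsplit(v, " "),
                         function(w) sum(w == "<MASK>"), numeric(1)) >= 1))
  expect_false(anyDuplicated(v) > 0)
  # brute-force oracle for one round on a 3-word candidate:
  # spans of length 1..3 replaced plus 4 insertion gaps
  w <- c("a", "b", "c")
  oracle <- character(0)
  for (s in 1:3) for (i in 1:(3 - s + 1)) {
    oracle <- c(oracle, paste(c(w[seq_len(i - 1)], "<MASK>",
                                if (i + s <= 3) w[(i + s):3]), collapse = " "))
  }
  for (g in 0:3) {
    oracle <- c(oracle, paste(c(w[seq_len(g)], "<MASK>",
                                if (g < 3) w[(g + 1):3]), collapse = " "))
  }
  expect_setequal(enumerate_masked_variants("a b c", max_extra_mask_rounds = 0),
                  unique(oracle))
})

test_that("masked-variant sampling is uniform and reproducible", {
  v <- enumerate_masked_variants("metal shapes", max_extra_mask_rounds = 0)
  expect_identical(sample_masked_candidates(v[1:3], n = 5), v[1:3])
  set.seed(1); s1 <- sample_masked_candidates(v, 4)
  set.seed(1); s2 <- sample_masked_candidates(v, 4)
  expect_identical(s1, s2)
  set.seed(2)
  counts <- table(factor(unlist(
    lapply(1:10000, function(i) sample_masked_candidates(v, 5))), levels = v))
  p <- 5 / 6
  expect_true(all(abs(counts / 10000 - p) < 3 * sqrt(p * (1 - p) / 10000)))
})

test_that("mask filling samples without replacement and conditions left-to-right", {
  vocab <- c("a", "b", "x", "y")
  degenerate <- proposal_model(vocab, function(words, pos) {
    stats::setNames(c(1, 0, 0, 0), vocab)
  })
  set.seed(3)
  expect_identical(fill_masks("<MASK> end", degenerate, fills = 5), "a end")
  two_support <- proposal_model(vocab, function(words, pos) {
    stats::setNames(c(0.5, 0.5, 0, 0), vocab)
  })
  set.seed(3)
  filled <- fill_masks("<MASK>", two_support, fills = 5)
  expect_setequal(filled, c("a", "b"))
  # second mask's distribution depends on the first fill
  bigram <- proposal_model(vocab, function(words, pos) {
    if (pos == 1) return(stats::setNames(c(0.5, 0.5, 0, 0), vocab))
    if (words[1] == "a") stats::setNames(c(0, 0, 1, 0), vocab)
    else stats::setNames(c(0, 0, 0, 1), vocab)
  })
  set.seed(4)
  out <- fill_masks("<MASK> <MASK>", bigram, fills = 5)
  expect_setequal(out, c("a x", "b y"))
  bad <- proposal_model(vocab, function(words, pos) {
    stats::setNames(c(2, 1, 0, 0), vocab)
  })
  expect_error(fill_masks("<MASK>", bad, fills = 2), "invalid categorical")
  expect_error(fill_masks("no mask here", degenerate), "no mask")
})

test_that("candidate scoring applies the layer-averaged correlation and length penalty", {
  ex <- tw_extractor()
  cap <- "bird"
  tgt <- ex$embed(cap)
  sc <- score_candidates(cap, tgt, ex, alpha = 0.1)
  expect_equal(sc$r, 1)
  expect_equal(sc$s, 1)   # l = 1 so the penalty is neutral
  long <- "bird eats snake quickly and quietly outside today near trees"
  sc10 <- score_candidates(long, tgt, ex, alpha = 0.1)
  expect_identical(sc10$l, 10)
  expect_equal(sc10$s, sc10$r * 10^(-0.1), tolerance = 1e-12)
  sc0 <- score_candidates(long, tgt, ex, alpha = 0)
  expect_equal(sc0$s, sc0$r)
  printed <- score_candidates(long, tgt, ex, alpha = 0.1,
                              penalty_form = "printed")
  expect_equal(printed$s, printed$r * 10^(0.1), tolerance = 1e-12)
  # a constant feature vector in one layer contributes zero correlation
  flat_ex <- feature_extractor(c("l1", "l2"), c(4, 4),
    embed = function(t) list(l1 = rep(1, 4), l2 = c(1, 2, 3, 5)),
    token_count = function(t) 1L)
  sflat <- score_candidates("anything", list(l1 = c(1, 2, 3, 4), l2 = c(1, 2, 3, 4)),
                            flat_ex, alpha = 0)
  expect_equal(sflat$r, mean(c(0, cor(c(1, 2, 3, 5), c(1, 2, 3, 4)))))
})

test_that("optimization is monotone, bounded, reproducible, and recovers toy captions", {
  ex <- tw_extractor()
  corpus <- tw_corpus(seed = 21)
  prop <- fit_toy_proposal(corpus)
  cap <- corpus$entries[[3]][1]   # a 3-word caption from the vocabulary
  tgt <- ex$embed(cap)
  cfg <- optimizer_config(iterations = 0, restarts = 1, seed = 5)
  expect_identical(optimize_description(tgt, ex, prop, cfg)$description, "<unk>")
  cfg <- optimizer_config(iterations = 100, restarts = 2, seed = 5,
                          stop_r = 1 - 1e-9)
  res <- optimize_description(tgt, ex, prop, cfg)
  expect_identical(res$description, cap)
  expect_equal(res$score$r, 1, tolerance = 1e-12)
  for (rs in unique(res$trace$restart)) {
    expect_true(all(diff(res$trace$s[res$trace$restart == rs]) >= -1e-12))
  }
  expect_true(all(res$trace$pool_size <= search_width_bound(cfg)))
  res2 <- optimize_description(tgt, ex, prop, cfg)
  expect_identical(res$trace, res2$trace)
})

test_that("alpha = 0 ranking reduces to the raw correlation ranking", {
  ex <- tw_extractor()
  tgt <- ex$embed("dog chases cat")
  cands <- c("dog chases cat quickly", "cat chases dog", "dog watches cat",
             "horse", "dog chases cat")
  s0 <- score_candidates(cands, tgt, ex, alpha = 0)
  expect_identical(order(-s0$s), order(-s0$r))
  expect_equal(s0$s, s0$r)
})
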