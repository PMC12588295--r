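test_that("Cohen's d and BH-FDR utilities match direct oracles", {
  x <- c(2, 4, 6, 8); y <- c(1, 2, 3, 4)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  p <- c(0.01, 0.04, 0.03, 0.2, 0.5)
  # direct step-up oracle
  o <- order(p); n <- length(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  oracle <- numeric(n); oracle[o] <- pmin(adj, 1)
  expect_equal(fdr_bh(p), oracle, tolerance = 1e-12)
})

test_that("bootstrap CI brackets the mean and respects the confidence level", {
  set.seed(30)
  x <- rnorm(200, 3)
  ci <- bootstrap_ci(x, n_boot = 2000)
  expect_lt(ci[["lower"]], mean(x))
  expect_gt(ci[["upper"]], mean(x))
  expect_lt(ci[["upper"]] - ci[["lower"]], 4 * sd(x) / sqrt(length(x)))
})

test_that("discriminability separates correct captions from irrelevant ones", {
  corpus <- caption_corpus(list(v1 = c("dog chases cat", "dog pursues cat"),
                                v2 = c("purple xylophones hum", "zithers buzz"),
                                v3 = c("quiet rivers flow", "streams murmur")))
  cfg <- metric_config("bleu4")
  d <- discriminability("dog chases cat", corpus, "v1", cfg)
  expect_gt(d$difference, 0)
  same <- caption_corpus(list(a = "one same caption", b = "one same caption"))
  d0 <- discriminability("one same caption", same, "a", metric_config("bleu4"))
  expect_equal(d0$difference, 0)
  # pooled-SD oracle for the effect size across samples
  res <- list(structure(list(correct_score = 0.9, incorrect_score = 0.2),
                        class = "discriminability_result"),
              structure(list(correct_score = 0.7, incorrect_score = 0.3),
                        class = "discriminability_result"),
              structure(list(correct_score = 0.8, incorrect_score = 0.1),
                        class = "discriminability_result"))
  expect_equal(discriminability_d(res),
               cohens_d(c(0.9, 0.7, 0.8), c(0.2, 0.3, 0.1)), tolerance = 1e-12)
})

test_that("text identification is perfect for self-matches and counts pairs correctly", {
  entries <- c(list(v1 = c("dog chases cat", "dog pursues cat")),
               stats::setNames(lapply(1:9, function(i) sprintf("filler%d words%d here%d", i, i, i)),
                               sprintf("f%d", 1:9)))
  corpus <- caption_corpus(entries)
  cfg <- metric_config("bleu4")
  curve <- identify_by_text("dog chases cat", corpus, "v1",
                            set_sizes = c(2, 5, 10), repeats = 20, config = cfg)
  expect_equal(curve$curve$accuracy, c(1, 1, 1))
  expect_equal(curve$curve$chance, 1 / c(2, 5, 10))
  two <- caption_corpus(list(a = "dog chases cat", b = "unrelated caption text"))
  c2 <- identify_by_text("dog chases cat", two, "a", set_sizes = 2,
                         repeats = 5, config = cfg)
  expect_equal(c2$curve$accuracy, 1)  # exactly one exhaustive comparison
  expect_error(identify_by_text("x", two, "zz", set_sizes = 2, config = cfg),
               "unknown")
})

test_that("identification under a random scorer sits at chance", {
  entries <- stats::setNames(as.list(sprintf("caption %d", 1:40)),
                             sprintf("v%02d", 1:40))
  corpus <- caption_corpus(entries)
  cfg <- metric_config(function(h, r) runif(1), aggregate = "mean")
  set.seed(31)
  curve <- identify_by_text("anything", corpus, "v01", set_sizes = 10,
                            repeats = 3000, config = cfg,
                            rescore_each_repeat = TRUE)
  expect_lt(abs(curve$curve$accuracy - 0.1), 3 * sqrt(0.1 * 0.9 / 3000))
})

test_that("pairwise feature identification scores exact, noisy and single-pair cases", {
  set.seed(32)
  cands <- matrix(rnorm(50 * 12), 50, 12)
  expect_equal(identify_pairwise_by_features(cands[7, ], cands, 7)$accuracy, 1)
  one <- identify_pairwise_by_features(cands[1, ], cands[1:2, ], 1)
  expect_true(one$accuracy %in% c(0, 1))
  expect_length(one$outcomes, 1)
  # decoded noise uncorrelated with symmetric candidates: near chance
  acc <- mean(vapply(1:200, function(i) {
    identify_pairwise_by_features(rnorm(12), cands, sample(50, 1))$accuracy
  }, numeric(1)))
  expect_lt(abs(acc - 0.5), 0.06)
})

test_that("generalizability angle follows the closed form with jackknife SE", {
  expect_equal(generalizability_angle(75, 75)$angle_deg, 0)
  expect_equal(generalizability_angle(80, 50)$angle_deg, 45)
  expect_equal(generalizability_angle(75, 62.5)$angle_deg,
               45 - atan(0.5) * 180 / pi, tolerance = 1e-10)
  expect_error(generalizability_angle(50, 60), "exceed chance")
  # monotone decreasing in imagery accuracy for fixed perception accuracy
  angles <- vapply(seq(50, 75, by = 5),
                   function(im) generalizability_angle(75, im)$angle_deg,
                   numeric(1))
  expect_true(all(diff(angles) < 0))
  set.seed(33)
  outc <- data.frame(perception = rbinom(40, 1, 0.8),
                     imagery = rbinom(40, 1, 0.65))
  g <- generalizability_angle(100 * mean(outc$perception),
                              100 * mean(outc$imagery), outcomes = outc)
  expect_gt(g$jackknife_se, 0)
  # direct jackknife oracle
  loo <- vapply(1:40, function(i) {
    generalizability_angle(100 * mean(outc$perception[-i]),
                           100 * mean(outc$imagery[-i]))$angle_deg
  }, numeric(1))
  expect_equal(g$jackknife_se, sqrt(39 / 40 * sum((loo - mean(loo))^2)),
               tolerance = 1e-12)
})

test_that("word shuffling enumerates distinct permutations and skips noun-poor text", {
  expect_length(shuffle_words("single"), 0)
  v3 <- shuffle_words("a b c")
  expect_length(v3, 5)   # 3! - 1 distinct non-identity permutations
  expect_false("a b c" %in% v3)
  vdup <- shuffle_words("a a b")
  expect_length(vdup, 2)  # multiset 3!/2! - 1
  tagger <- tw_noun_tagger()
  sk <- shuffle_words("bird eats quickly", mode = "nouns", noun_tagger = tagger)
  expect_true(sk$skipped)
  vn <- shuffle_words("bird eats snake", mode = "nouns", noun_tagger = tagger)
  expect_identical(vn, "snake eats bird")  # only noun positions move
  set.seed(34)
  long <- shuffle_words(paste(letters[1:9], collapse = " "), max_variants = 50)
  expect_length(long, 50)
  expect_false(anyDuplicated(long) > 0)
})

test_that("pseudo-log-likelihood matches closed forms and is non-positive", {
  vocab <- c("a", "b", "c", "d")
  oracle_true <- proposal_model(vocab, function(words, pos) {
    # probability 1 on the masked word's true identity encoded in the test
    truth <- c("a", "b", "c")
    stats::setNames(as.numeric(vocab == truth[pos]), vocab)
  })
  expect_equal(pseudo_log_likelihood("a b c", oracle_true), 0)
  unif <- uniform_proposal_model(vocab)
  expect_equal(pseudo_log_likelihood("a b c", unif), 3 * log(1 / 4),
               tolerance = 1e-12)
  corpus <- tw_corpus(seed = 35)
  prop <- fit_toy_proposal(corpus)
  for (cap in unlist(corpus$entries[1:3])) {
    expect_lte(pseudo_log_likelihood(cap, prop), 0)
  }
})

test_that("shuffle impact reports rank the original under order-sensitive features", {
  ex <- tw_extractor()
  desc <- "bird eats snake quickly"
  shuffles <- shuffle_words(desc)
  refs <- c("bird eats snake", "bird eats snake outside")
  prop <- fit_toy_proposal(tw_corpus(seed = 36))
  rep1 <- shuffle_impact_report(desc, shuffles, refs,
                                metric_config("feature_correlation",
                                              extractor = ex),
                                extractor = ex, proposal = prop)
  expect_equal(rep1$rank_of_original, 1)
  expect_equal(nrow(rep1$table), length(shuffles) + 1)
  expect_equal(rep1$table$target_r[1], 1)
  expect_equal(rep1$table$corr_distance[1], 0)
  expect_true(all(rep1$table$corr_distance >= 0 & rep1$table$corr_distance <= 2))
  expect_true(rep1$most_fluent_variant %in% shuffles)
  expect_equal(sum(rep1$table$is_original), 1)
  # an order-insensitive extractor cannot separate original from variants
  bag_ex <- feature_extractor("bag", 32,
    embed = function(t) {
      full <- ex$embed(t); list(bag = full$bag)
    },
    token_count = ex$token_count)
  rep2 <- shuffle_impact_report(desc, shuffles, refs,
                                metric_config("feature_correlation",
                                              extractor = bag_ex),
                                extractor = bag_ex)
  expect_true(all(abs(rep2$table$target_r - 1) < 1e-12))
  # single-variant report has exactly two rows
  rep3 <- shuffle_impact_report(desc, shuffles[1], refs,
                                metric_config("bleu4"), extractor = ex)
  expect_equal(nrow(rep3$table), 2)
})

test_that("Self-BLEU measures within-group diversity", {
  same <- c("a b c d", "a b c d", "a b c d")
  expect_equal(unname(self_bleu(same, rep("g", 3))), 1)
  mixed <- c("a b c d", "a b c d", "w x y z")
  got <- unname(self_bleu(mixed, rep("g", 3)))
  # oracle: members 1-2 score 1 against each other; member 3 is disjoint
  s3 <- exp(mean(log(0.1 / c(4, 3, 2, 1))))
  expect_equal(got, (1 + 1 + s3) / 3, tolerance = 1e-12)
  two_groups <- self_bleu(c("a b", "a b", "p q", "r s"),
                          c("g1", "g1", "g2", "g2"))
  expect_equal(unname(two_groups["g1"]), 1)
  expect_lt(unname(two_groups["g2"]), 0.2)
})
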