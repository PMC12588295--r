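test_that("ridge solution matches a normal-equations oracle", {
  set.seed(10)
  X <- matrix(rnorm(15), 5, 3)
  Y <- matrix(rnorm(10), 5, 2)
  fit <- fit_ridge(X, Y, lambda = 1)
  # independent oracle: centered (X'X + lambda I)^-1 X'Y
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  W <- solve(crossprod(Xc) + diag(3), crossprod(Xc, Yc))
  expect_equal(unname(fit$W), unname(W), tolerance = 1e-8)
  expect_equal(fit$b, colMeans(Y) - as.vector(colMeans(X) %*% W),
               tolerance = 1e-8)
})

test_that("ridge limits: heavy shrinkage, exact interpolation, pseudo-inverse fallback", {
  set.seed(11)
  X <- matrix(rnorm(40), 10, 4)
  Y <- matrix(rnorm(20), 10, 2)
  big <- fit_ridge(X, Y, lambda = 1e12)
  expect_equal(max(abs(big$W)), 0, tolerance = 1e-8)
  expect_equal(big$b, colMeans(Y), tolerance = 1e-8)
  ident <- fit_ridge(X, X, lambda = 0)
  expect_equal(predict_ridge(ident, X), X, tolerance = 1e-10,
               ignore_attr = TRUE)
  Xd <- cbind(X, X[, 1])  # rank deficient
  expect_warning(fit_ridge(Xd, Y, lambda = 0), "pseudo-inverse")
})

test_that("training residual norm is non-decreasing in lambda", {
  set.seed(12)
  X <- matrix(rnorm(200), 20, 10)
  Y <- matrix(rnorm(60), 20, 3)
  rss <- vapply(c(0, 1, 10, 100, 1000), function(lam) {
    sum((Y - predict_ridge(fit_ridge(X, Y, lam), X))^2)
  }, numeric(1))
  expect_true(all(diff(rss) >= -1e-8))
})

test_that("cross-validation plan partitions samples by run at both levels", {
  runs <- rep(sprintf("r%02d", 1:12), each = 5)
  plan <- cv_plan(runs, n_outer = 6, n_inner = 5)
  all_test <- sort(unlist(lapply(plan$outer, `[[`, "test")))
  expect_identical(all_test, seq_along(runs))
  for (fd in plan$outer) {
    expect_length(intersect(fd$train, fd$test), 0)
    expect_false(any(runs[fd$train] %in% runs[fd$test]))
    inner_test <- sort(unlist(lapply(fd$inner, `[[`, "test")))
    expect_identical(inner_test, sort(fd$train))
    for (f in fd$inner) {
      expect_length(intersect(f$train, f$test), 0)
      expect_true(all(c(f$train, f$test) %in% fd$train))
    }
  }
  expect_error(cv_plan(rep("a", 10), n_outer = 6), "distinct runs")
})

test_that("regularization selection maximizes held-out correlation", {
  grid <- default_lambda_grid()
  expect_length(grid, 10)
  expect_equal(range(grid), c(10, 10000))
  expect_equal(select_regularization(NULL, NULL, grid = 42, folds = NULL)$lambda, 42)
  sys0 <- tw_linear_system(n = 60, noise_sd = 0, seed = 13)
  plan <- cv_plan(sys0$brain$runs, n_outer = 3, n_inner = 2)
  folds <- plan$outer
  X <- sys0$brain$X
  Y <- sys0$features$layers$bag
  sel <- select_regularization(Y, X, grid = grid, folds = folds)
  expect_equal(sel$lambda, 10)  # noiseless: least shrinkage wins
  # winner agrees with exhaustive evaluation of the grid
  scores <- vapply(grid, function(lam) {
    mean(vapply(folds, function(fd) {
      f <- fit_ridge(Y[fd$train, ], X[fd$train, ], lam)
      mean(diag(cor(predict_ridge(f, Y[fd$test, ]), X[fd$test, ])), na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(sel$lambda, grid[which.max(scores)])
})

test_that("decoders recover a noiseless linear system and serialize exactly", {
  sys0 <- tw_linear_system(n = 60, noise_sd = 0, seed = 14)
  plan <- cv_plan(sys0$brain$runs, n_outer = 6, n_inner = 5)
  bank <- train_feature_decoders(sys0$brain, sys0$features, plan)
  dec <- decode_features(bank, sys0$brain)
  acc <- decoding_accuracy(dec, sys0$features)
  expect_true(all(unlist(acc) >= 0.99))
  # constant brain input decodes to the intercept
  flat <- brain_data(matrix(0, 3, ncol(sys0$brain$X)), runs = rep("r", 3))
  dflat <- decode_features(bank, flat)
  expect_equal(unname(dflat$layers$bag[1, ]), unname(bank$layers$bag$b))
  expect_equal(dflat$layers$bag[1, ], dflat$layers$bag[3, ])
  # save/load round-trip reproduces decoding bit-for-bit
  path <- tempfile(fileext = ".rds")
  save_ridge_bank(bank, path)
  expect_identical(decode_features(load_ridge_bank(path), sys0$brain)$layers,
                   dec$layers)
})

test_that("held-out decoding has no leakage from test folds", {
  sys1 <- tw_linear_system(n = 48, noise_sd = 0.1, seed = 15)
  plan <- cv_plan(sys1$brain$runs, n_outer = 6, n_inner = 5)
  cvd <- crossval_decode_features(sys1$brain, sys1$features, plan)
  # scramble the fold-1 target rows: predictions for fold 1 must not change
  f1 <- plan$outer[[1]]$test
  scr <- sys1$features
  scr$layers$bag[f1, ] <- scr$layers$bag[rev(f1), ]
  scr2 <- layer_features(scr$layers, sys1$features$sample_ids)
  cvd2 <- crossval_decode_features(sys1$brain, scr2, plan)
  expect_identical(cvd$predictions$layers$bag[f1, ],
                   cvd2$predictions$layers$bag[f1, ])
})

test_that("encoding models pick the generating layer per voxel", {
  set.seed(16)
  n <- 60
  lf <- layer_features(list(l1 = matrix(rnorm(n * 6), n),
                            l2 = matrix(rnorm(n * 6), n)))
  W2 <- matrix(rnorm(6 * 8), 6, 8)
  noise <- matrix(rnorm(n * 8, sd = 0.05), n, 8)
  brain <- brain_data(lf$layers$l2 %*% W2 + noise,
                      runs = rep(sprintf("r%d", 1:6), each = 10))
  plan <- cv_plan(brain$runs, n_outer = 3, n_inner = 2)
  map <- train_voxel_encoders(lf, brain, plan)
  expect_true(all(map$best_layer == 2))
  expect_true(all(map$relative_depth == 1))
  expect_true(mean(map$combined_cor) > 0.9)
  # identical layers tie to the shallowest
  lfsame <- layer_features(list(l1 = lf$layers$l2, l2 = lf$layers$l2))
  map2 <- train_voxel_encoders(lfsame, brain, plan)
  expect_true(all(map2$best_layer == 1))
  # a pure-noise voxel shows near-zero encoding accuracy
  brain_noise <- brain_data(cbind(brain$X, rnorm(n)), runs = brain$runs)
  map3 <- train_voxel_encoders(lf, brain_noise, plan)
  expect_lt(abs(map3$combined_cor[9]), 0.35)
})

test_that("voxel selection ranks by best-layer correlation with index tie-break", {
  map <- structure(list(layer_cor = cbind(c(0.1, 0.8, 0.3, 0.8, -0.2),
                                          c(0.05, 0.2, 0.6, 0.1, 0.0)),
                        best_layer = c(1L, 1L, 2L, 1L, 2L)),
                   class = "encoding_map")
  expect_identical(select_voxels_by_encoding(map, k = 10), c(2L, 4L, 3L, 1L, 5L))
  expect_identical(select_voxels_by_encoding(map, k = 1), 2L)
  expect_identical(select_voxels_by_encoding(map, k = 3), c(2L, 4L, 3L))
})

test_that("Deming parity angles match closed forms and are symmetric", {
  a <- c(55, 60, 65, 72, 80, 90)
  p0 <- deming_parity_angle(a, a)
  expect_equal(p0$slope, 1, tolerance = 1e-12)
  expect_equal(p0$angle_deviation_deg, 0, tolerance = 1e-10)
  p2 <- deming_parity_angle(a, 2 * a)
  expect_equal(p2$angle_deviation_deg, 45 - atan(2) * 180 / pi,
               tolerance = 1e-10)
  ph <- deming_parity_angle(a, a / 2)
  expect_equal(ph$angle_deviation_deg, 45 - atan(0.5) * 180 / pi,
               tolerance = 1e-10)
  set.seed(17)
  x <- rnorm(20); y <- 1.7 * x + 3
  expect_equal(deming_parity_angle(x, y)$slope,
               1 / deming_parity_angle(y, x)$slope, tolerance = 1e-10)
  expect_error(deming_parity_angle(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(deming_parity_angle(1:2, 1:2), "3 paired")
})
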