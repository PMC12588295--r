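#' Default regularization grid
#'
#' Ten coefficients log-spaced between 10 and 10,000.
#' @return Numeric vector of length 10.
#' @export
default_lambda_grid <- function() 10^seq(1, 4, length.out = 10)

#' Closed-form ridge regression with unpenalized intercept
#'
#' Solves the L2-regularized least-squares problem for a multi-output target
#' via the SVD of the column-centered design: slope weights shrink toward 0
#' as `lambda` grows while the intercept tends to the column means of `Y`.
#' With `lambda = 0` and a rank-deficient design, the minimum-norm
#' (pseudo-inverse) solution is returned with a warning.
#'
#' @param X Samples-by-predictors matrix.
#' @param Y Samples-by-outputs matrix (or vector).
#' @param lambda Non-negative scalar.
#' @return List of class `ridge_fit` with `W` (predictors x outputs),
#'   `b` (intercepts), and `lambda`.
#' @export
fit_ridge <- function(X, Y, lambda) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), length(lambda) == 1, lambda >= 0)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  sv <- svd(Xc)
  d <- sv$d
  tol <- max(dim(Xc)) * max(d, 0) * .Machine$double.eps
  if (lambda == 0) {
    keep <- d > tol
    if (sum(keep) < ncol(X)) {
      warning("rank-deficient design with lambda = 0; using pseudo-inverse solution")
    }
    shrink <- ifelse(keep, 1 / pmax(d, tol), 0)
  } else {
    shrink <- d / (d^2 + lambda)
  }
  W <- sv$v %*% (shrink * (t(sv$u) %*% Yc))
  dimnames(W) <- list(colnames(X), colnames(Y))
  structure(list(W = W, b = ym - as.vector(xm %*% W), lambda = lambda),
            class = "ridge_fit")
}

#' @rdname fit_ridge
#' @param fit A `ridge_fit`.
#' @param newX New design matrix.
#' @export
predict_ridge <- function(fit, newX) {
  sweep(as.matrix(newX) %*% fit$W, 2, fit$b, `+`)
}

#' Run-grouped nested cross-validation plan
#'
#' Outer folds group scanner runs (default 6 folds); inner folds (default 5)
#' are nested within each outer training set. Folds are disjoint and
#' exhaustive at both levels, so no sample ever appears in both the training
#' and test side of the same fold.
#'
#' @param runs Run label per sample.
#' @param n_outer,n_inner Fold counts.
#' @return List of class `cv_plan`: `outer` is a list of folds, each with
#'   `train`/`test` sample indices and an `inner` list of nested folds
#'   (indices into the full sample set, all within the outer training set).
#' @export
cv_plan <- function(runs, n_outer = 6, n_inner = 5) {
  runs <- as.character(runs)
  u <- unique(runs)
  if (length(u) < n_outer) stop_user("need at least n_outer distinct runs")
  fold_of_run <- stats::setNames(((seq_along(u) - 1) %% n_outer) + 1, u)
  outer <- lapply(seq_len(n_outer), function(k) {
    test <- which(unname(fold_of_run[runs]) == k)
    train <- setdiff(seq_along(runs), test)
    train_runs <- unique(runs[train])
    if (length(train_runs) < n_inner) stop_user("need at least n_inner runs in each outer training set")
    ifold <- stats::setNames(((seq_along(train_runs) - 1) %% n_inner) + 1, train_runs)
    inner <- lapply(seq_len(n_inner), function(j) {
      itest <- train[unname(ifold[runs[train]]) == j]
      list(train = setdiff(train, itest), test = itest)
    })
    list(train = train, test = test, inner = inner)
  })
  structure(list(outer = outer, runs = runs, n_outer = n_outer,
                 n_inner = n_inner), class = "cv_plan")
}

# mean held-out per-unit correlation for each lambda over a list of folds
cv_lambda_scores <- function(X, Y, grid, folds) {
  scores <- vapply(grid, function(lam) {
    fold_means <- vapply(folds, function(fd) {
      fit <- fit_ridge(X[fd$train, , drop = FALSE], Y[fd$train, , drop = FALSE], lam)
      r <- col_cor(predict_ridge(fit, X[fd$test, , drop = FALSE]),
                   Y[fd$test, , drop = FALSE])
      mean(r, na.rm = TRUE)
    }, numeric(1))
    mean(fold_means, na.rm = TRUE)
  }, numeric(1))
  scores
}

#' Select a ridge regularization coefficient by cross-validation
#'
#' The selected coefficient maximizes the mean held-out Pearson correlation
#' averaged over all output units (one shared lambda per layer and
#' direction); units with undefined correlation (constant output) are
#' excluded from the mean. Ties break to the smallest grid value.
#'
#' @param X,Y Aligned design/target matrices.
#' @param grid Candidate coefficients (default [default_lambda_grid()]).
#' @param folds List of folds with `train`/`test` indices (e.g. the `inner`
#'   element of a [cv_plan()] outer fold, or the outer folds themselves).
#' @return List with `lambda` (the winner) and `scores` (mean correlation per
#'   grid value).
#' @export
select_regularization <- function(X, Y, grid = default_lambda_grid(), folds) {
  if (length(grid) == 0) stop_user("empty regularization grid")
  if (length(grid) == 1) return(list(lambda = grid, scores = NA_real_))
  scores <- cv_lambda_scores(as.matrix(X), as.matrix(Y), grid, folds)
  list(lambda = grid[which.max(scores)], scores = scores)
}

#' Train layerwise feature decoders (brain to features)
#'
#' One ridge model per layer (one linear readout per feature unit) mapping
#' multivoxel patterns to normalized feature values. The regularization
#' coefficient is chosen per layer by cross-validation over the supplied
#' folds, then the final model is refit on all training rows.
#'
#' @param brain A [brain_data()].
#' @param features Aligned [layer_features()] (normalized).
#' @param plan A [cv_plan()]; its outer folds drive lambda selection.
#' @param voxel_subset Optional voxel indices to train on.
#' @param grid Regularization grid.
#' @return A `ridge_bank`: per-layer `ridge_fit`s plus the lambda grid,
#'   direction and voxel subset.
#' @export
train_feature_decoders <- function(brain, features, plan,
                                   voxel_subset = NULL,
                                   grid = default_lambda_grid()) {
  stopifnot(inherits(brain, "brain_data"), inherits(features, "layer_features"))
  if (!identical(brain$sample_ids, features$sample_ids)) {
    stop_user("brain and feature sample ids are not aligned")
  }
  voxel_subset <- voxel_subset %||% seq_len(ncol(brain$X))
  X <- brain$X[, voxel_subset, drop = FALSE]
  models <- lapply(features$layers, function(Y) {
    sel <- select_regularization(X, Y, grid, folds = plan$outer)
    fit <- fit_ridge(X, Y, sel$lambda)
    fit$cv_scores <- sel$scores
    fit
  })
  structure(list(layers = models, grid = grid, direction = "decode",
                 voxel_subset = voxel_subset), class = "ridge_bank")
}

#' Decode layerwise features from brain activity
#'
#' @param bank A `ridge_bank` from [train_feature_decoders()].
#' @param brain A [brain_data()].
#' @return Predicted [layer_features()].
#' @export
decode_features <- function(bank, brain) {
  stopifnot(inherits(bank, "ridge_bank"), inherits(brain, "brain_data"))
  X <- brain$X[, bank$voxel_subset, drop = FALSE]
  layer_features(lapply(bank$layers, function(fit) predict_ridge(fit, X)),
                 sample_ids = brain$sample_ids)
}

#' Per-unit decoding accuracy
#'
#' @param predicted,truth Aligned [layer_features()].
#' @return Named list of per-unit Pearson correlations per layer.
#' @export
decoding_accuracy <- function(predicted, truth) {
  Map(function(P, Tr) col_cor(P, Tr), predicted$layers,
      truth$layers[names(predicted$layers)])
}

#' Cross-validated feature decoding
#'
#' For each outer fold, the regularization coefficient is chosen on the
#' nested inner folds, a decoder is fit on the outer training rows, and the
#' held-out rows are predicted — yielding out-of-sample predictions for every
#' sample with no leakage from any test fold into training.
#'
#' @inheritParams train_feature_decoders
#' @return List with `predictions` ([layer_features()] of held-out
#'   predictions), `per_unit_cor` (per layer), and `lambdas`
#'   (layer x outer-fold matrix).
#' @export
crossval_decode_features <- function(brain, features, plan,
                                     voxel_subset = NULL,
                                     grid = default_lambda_grid()) {
  stopifnot(inherits(brain, "brain_data"), inherits(features, "layer_features"))
  voxel_subset <- voxel_subset %||% seq_len(ncol(brain$X))
  X <- brain$X[, voxel_subset, drop = FALSE]
  L <- names(features$layers)
  preds <- lapply(features$layers, function(Y) Y * NA_real_)
  lambdas <- matrix(NA_real_, length(L), length(plan$outer),
                    dimnames = list(L, NULL))
  for (k in seq_along(plan$outer)) {
    fd <- plan$outer[[k]]
    for (ln in L) {
      Y <- features$layers[[ln]]
      sel <- select_regularization(X[fd$train, , drop = FALSE],
                                   Y[fd$train, , drop = FALSE], grid,
                                   folds = lapply(fd$inner, function(f) {
                                     list(train = match(f$train, fd$train),
                                          test = match(f$test, fd$train))
                                   }))
      fit <- fit_ridge(X[fd$train, , drop = FALSE], Y[fd$train, , drop = FALSE],
                       sel$lambda)
      preds[[ln]][fd$test, ] <- predict_ridge(fit, X[fd$test, , drop = FALSE])
      lambdas[ln, k] <- sel$lambda
    }
  }
  pred_lf <- layer_features(preds, sample_ids = features$sample_ids)
  list(predictions = pred_lf,
       per_unit_cor = decoding_accuracy(pred_lf, features),
       lambdas = lambdas)
}

#' Voxelwise encoding models with per-voxel layer selection
#'
#' Fits ridge encoding models (features to voxel amplitudes) per layer within
#' an outer cross-validation; the best layer for each voxel is determined
#' only from training-side information (inner-fold held-out correlations),
#' and final held-out predictions are assembled from each voxel's best layer.
#' Ties in layer selection break to the shallowest layer.
#'
#' @param features [layer_features()] predictors.
#' @param brain [brain_data()] targets.
#' @param plan A [cv_plan()].
#' @param grid Regularization grid.
#' @return An `encoding_map` with `layer_cor` (voxels x layers held-out
#'   correlations), `best_layer` (index per voxel), `relative_depth` in
#'   [0, 1], `combined_cor` (per-voxel correlation of best-layer
#'   predictions), and `predictions`.
#' @export
train_voxel_encoders <- function(features, brain, plan,
                                 grid = default_lambda_grid()) {
  stopifnot(inherits(brain, "brain_data"), inherits(features, "layer_features"))
  L <- names(features$layers)
  V <- ncol(brain$X)
  n <- nrow(brain$X)
  K <- length(plan$outer)
  pred_by_layer <- lapply(L, function(ln) matrix(NA_real_, n, V))
  names(pred_by_layer) <- L
  inner_cor <- array(NA_real_, c(V, length(L), K), dimnames = list(NULL, L, NULL))
  combined_pred <- matrix(NA_real_, n, V)
  for (k in seq_len(K)) {
    fd <- plan$outer[[k]]
    inner_folds <- lapply(fd$inner, function(f) {
      list(train = match(f$train, fd$train), test = match(f$test, fd$train))
    })
    for (li in seq_along(L)) {
      Xl <- features$layers[[L[li]]]
      sel <- select_regularization(Xl[fd$train, , drop = FALSE],
                                   brain$X[fd$train, , drop = FALSE],
                                   grid, folds = inner_folds)
      # per-voxel inner-CV correlation at the chosen lambda (training side)
      ip <- matrix(NA_real_, length(fd$train), V)
      for (f in inner_folds) {
        fit <- fit_ridge(Xl[fd$train[f$train], , drop = FALSE],
                         brain$X[fd$train[f$train], , drop = FALSE], sel$lambda)
        ip[f$test, ] <- predict_ridge(fit, Xl[fd$train[f$test], , drop = FALSE])
      }
      inner_cor[, li, k] <- col_cor(ip, brain$X[fd$train, , drop = FALSE])
      fit <- fit_ridge(Xl[fd$train, , drop = FALSE],
                       brain$X[fd$train, , drop = FALSE], sel$lambda)
      pred_by_layer[[li]][fd$test, ] <- predict_ridge(fit, Xl[fd$test, , drop = FALSE])
    }
    best_k <- apply(inner_cor[, , k, drop = FALSE], 1, function(r) which.max(r))
    for (v in seq_len(V)) {
      combined_pred[fd$test, v] <- pred_by_layer[[best_k[v]]][fd$test, v]
    }
  }
  layer_cor <- vapply(pred_by_layer, function(P) col_cor(P, brain$X),
                      numeric(V))
  mean_inner <- apply(inner_cor, c(1, 2), mean, na.rm = TRUE)
  best_layer <- apply(mean_inner, 1, which.max)  # which.max -> lowest index on ties
  structure(list(layer_cor = layer_cor,
                 best_layer = best_layer,
                 relative_depth = (best_layer - 1) / max(1, length(L) - 1),
                 combined_cor = col_cor(combined_pred, brain$X),
                 predictions = combined_pred,
                 layer_names = L),
            class = "encoding_map")
}

#' Select voxels by encoding accuracy
#'
#' Returns the indices of the top `k` voxels ranked by their best-layer
#' encoding correlation (deterministic tie-break by voxel index); all voxels
#' when `k` exceeds the voxel count. Used to restrict decoder training to the
#' voxels best predicted by the target feature set (up to 50,000 in a
#' whole-brain analysis).
#'
#' @param map An `encoding_map`.
#' @param k Maximum number of voxels (default 50000).
#' @return Integer vector of voxel indices, best first.
#' @export
select_voxels_by_encoding <- function(map, k = 50000) {
  stopifnot(inherits(map, "encoding_map"))
  best <- map$layer_cor[cbind(seq_len(nrow(map$layer_cor)), map$best_layer)]
  ord <- order(-best, seq_along(best))
  ord[seq_len(min(k, length(best)))]
}

#' Deming-regression deviation from parity
#'
#' Fits an errors-in-variables (Deming) line through paired accuracies of two
#' models, assuming an equal error-variance ratio, and converts the slope to
#' an angular deviation from the 45-degree parity line:
#' deviation = 45 - atan(slope) * 180 / pi. A positive deviation means model
#' A (the x-axis) outperforms model B.
#'
#' @param acc_a,acc_b Paired accuracy vectors (length >= 3).
#' @param ratio Error-variance ratio (default 1).
#' @return List of class `parity_comparison` with `slope`, `intercept`,
#'   `angle_deviation_deg` and `n`.
#' @export
deming_parity_angle <- function(acc_a, acc_b, ratio = 1) {
  stopifnot(length(acc_a) == length(acc_b))
  if (length(acc_a) < 3) stop_user("need at least 3 paired points")
  sxx <- stats::var(acc_a); syy <- stats::var(acc_b)
  sxy <- stats::cov(acc_a, acc_b)
  if (sxx == 0 && syy == 0) stop_user("zero variance on both axes")
  slope <- if (sxy == 0) {
    if (sxx == 0) Inf else 0
  } else {
    (syy - ratio * sxx + sqrt((syy - ratio * sxx)^2 + 4 * ratio * sxy^2)) /
      (2 * sxy)
  }
  angle <- 45 - atan(slope) * 180 / pi
  structure(list(slope = slope,
                 intercept = mean(acc_b) - slope * mean(acc_a),
                 angle_deviation_deg = angle, n = length(acc_a)),
            class = "parity_comparison")
}

#' Save / load a ridge bank (exact round-trip)
#'
#' @param bank A `ridge_bank`.
#' @param path File path (RDS).
#' @export
save_ridge_bank <- function(bank, path) {
  stopifnot(inherits(bank, "ridge_bank"))
  saveRDS(bank, path)
  invisible(path)
}

#' @rdname save_ridge_bank
#' @export
load_ridge_bank <- function(path) {
  if (!file.exists(path)) stop_user("ridge bank not found: ", path)
  bank <- readRDS(path)
  stopifnot(inherits(bank, "ridge_bank"))
  bank
}
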