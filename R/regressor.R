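# Desk-scale pose regressor exercising the three scoring variants.
#
# Pipeline per sample: synthetic raster -> gradient-orientation feature map
# (extract_features) -> scoring (uniform / variance / conv1x1) -> top-k
# score-weighted aggregation; the regression design concatenates the
# aggregated vector with the score-weighted per-cell features, and yaw,
# pitch and roll are fitted by closed-form ridge regression on standardized
# columns. For the conv1x1 variant the kernel w is fitted jointly by seeded
# BFGS on the training mean squared error. Everything is deterministic given
# the seed. This is deliberately a minimal, CPU-scale pipeline whose only
# purpose is to compare the scoring variants under identical conditions.

regressor_design_row <- function(fmap, scoring, w, k) {
  s <- switch(scoring,
    uniform = score_uniform(fmap),
    variance = score_variance(fmap),
    conv1x1 = score_conv1x1(fmap, w)
  )
  agg <- aggregate_features(fmap, s, k)
  d <- dim(fmap)
  scored <- as.numeric(sweep(fmap, c(1, 2), s, "*"))
  c(agg, scored)
}

build_design <- function(fmaps, scoring, w, k) {
  do.call(rbind, purrr::map(fmaps, regressor_design_row,
                            scoring = scoring, w = w, k = k))
}

ridge_fit <- function(X, Y, lambda) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  y_ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, y_ctr)
  beta <- solve(crossprod(Xs) + lambda * diag(ncol(Xs)), crossprod(Xs, Yc))
  list(beta = beta, center = ctr, scale = scl, y_center = y_ctr)
}

ridge_predict <- function(fit, X) {
  Xs <- scale(X, center = fit$center, scale = fit$scale)
  sweep(Xs %*% fit$beta, 2, fit$y_center, "+")
}

#' Fit the toy scoring-comparison pose regressor
#'
#' Trains a deterministic pose regressor on the training split of a synthetic
#' dataset, using one of the three pixelwise scoring variants. See the
#' package vignette for the pipeline; this regressor exists to compare the
#' scoring functions under identical, reproducible conditions, not to model
#' real images.
#'
#' @param dataset A [generate_dataset()] result (needs >= 50 training
#'   samples).
#' @param scoring `"uniform"`, `"variance"` or `"conv1x1"`.
#' @param seed Seed for the conv1x1 kernel initialization.
#' @param lambda Ridge penalty on standardized columns.
#' @param k Top-k aggregation size.
#' @param grid,n_bins Feature-map geometry, passed to [extract_features()].
#' @param rasters Optional precomputed list of rasters for all dataset
#'   samples, to avoid re-rendering when fitting several variants.
#' @return An object of class `pose_regressor`. Use `predict()` with a list
#'   of rasters (or a `synthetic_dataset` plus `split`) to obtain a pose
#'   tibble, and [glance()] for a fit summary.
#' @export
fit_pose_regressor <- function(dataset,
                               scoring = c("uniform", "variance", "conv1x1"),
                               seed = 1L, lambda = 1, k = 9,
                               grid = c(6, 6), n_bins = 8,
                               rasters = NULL) {
  scoring <- match.arg(scoring)
  stopifnot(inherits(dataset, "synthetic_dataset"))
  train_idx <- which(dataset$manifest$split == "train")
  if (length(train_idx) < 50) {
    cp_abort(sprintf("Need at least 50 training samples, got %d.",
                     length(train_idx)), "insufficient_data")
  }
  if (is.null(rasters)) {
    rasters <- purrr::map(dataset$samples, rasterize_sample, cam = dataset$cam)
  }
  fmaps <- purrr::map(rasters[train_idx], extract_features,
                      grid = grid, n_bins = n_bins)
  Y <- as.matrix(dataset$manifest[train_idx,
                                  c("yaw_deg", "pitch_deg", "roll_deg")])

  w <- NULL
  if (scoring == "conv1x1") {
    objective <- function(wv) {
      X <- build_design(fmaps, "conv1x1", wv, k)
      fit <- ridge_fit(X, Y, lambda)
      mean((ridge_predict(fit, X) - Y)^2)
    }
    w0 <- withr::with_seed(as.integer(seed), rnorm(n_bins, sd = 0.1))
    opt <- optim(w0, objective, method = "BFGS",
                 control = list(maxit = 25, reltol = 1e-6))
    w <- opt$par
  }

  X <- build_design(fmaps, scoring, w, k)
  fit <- ridge_fit(X, Y, lambda)
  train_pred <- ridge_predict(fit, X)
  train_mae <- mae_pose(
    pose_angles(train_pred[, 1], train_pred[, 2], train_pred[, 3]),
    pose_angles(Y[, 1], Y[, 2], Y[, 3])
  )

  structure(
    list(scoring = scoring, w = w, k = k, lambda = lambda, grid = grid,
         n_bins = n_bins, fit = fit, n_train = length(train_idx),
         seed = as.integer(seed), train_mae = train_mae),
    class = "pose_regressor"
  )
}

#' @export
print.pose_regressor <- function(x, ...) {
  cat(sprintf(
    "<pose_regressor> scoring '%s', %d training samples, train MAE %.2f deg\n",
    x$scoring, x$n_train, x$train_mae
  ))
  invisible(x)
}

#' Predict poses with a fitted toy regressor
#'
#' @param object A `pose_regressor`.
#' @param newdata A list of raster matrices, or a `synthetic_dataset`.
#' @param split When `newdata` is a dataset: which split to predict
#'   (`"test"`, `"val"`, `"train"` or `"all"`).
#' @param ... Unused.
#' @return A pose tibble with one row per raster.
#' @method predict pose_regressor
#' @export
predict.pose_regressor <- function(object, newdata, split = "test", ...) {
  if (inherits(newdata, "synthetic_dataset")) {
    idx <- if (identical(split, "all")) seq_len(nrow(newdata$manifest)) else
      which(newdata$manifest$split == split)
    newdata <- purrr::map(newdata$samples[idx], rasterize_sample,
                          cam = newdata$cam)
  }
  fmaps <- purrr::map(newdata, extract_features,
                      grid = object$grid, n_bins = object$n_bins)
  X <- build_design(fmaps, object$scoring, object$w, object$k)
  pred <- ridge_predict(object$fit, X)
  pose_angles(pred[, 1], pred[, 2], pred[, 3])
}

#' @rdname fit_pose_regressor
#' @param x A `pose_regressor`.
#' @param ... Unused.
#' @method glance pose_regressor
#' @export
glance.pose_regressor <- function(x, ...) {
  tibble(scoring = x$scoring, n_train = x$n_train, lambda = x$lambda,
         k = x$k, train_mae = x$train_mae, seed = x$seed)
}

#' Compare the three scoring variants on one synthetic dataset
#'
#' Reproduces the structure of a scoring-function ablation: one regressor per
#' scoring variant (uniform / conv1x1 / variance), all trained on the same
#' training split and evaluated on the same held-out test split, alongside a
#' predict-the-training-mean baseline. Reported MAEs use both the per-angle
#' convention and the vector L2 norm.
#'
#' @param dataset A [generate_dataset()] result with train and test splits.
#' @param seed Seed forwarded to the conv1x1 kernel fit.
#' @param ... Passed to [fit_pose_regressor()].
#' @return A tibble of class `scoring_comparison` with columns `model`,
#'   `mae_per_angle`, `mae_l2`, `n_train`, `n_test`.
#' @export
compare_scoring <- function(dataset, seed = 1L, ...) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  rasters <- purrr::map(dataset$samples, rasterize_sample, cam = dataset$cam)
  train_idx <- which(dataset$manifest$split == "train")
  test_idx <- which(dataset$manifest$split == "test")
  truth <- pose_angles(dataset$manifest$yaw_deg[test_idx],
                       dataset$manifest$pitch_deg[test_idx],
                       dataset$manifest$roll_deg[test_idx])

  train_mean <- colMeans(dataset$manifest[train_idx,
                                          c("yaw_deg", "pitch_deg", "roll_deg")])
  baseline <- pose_angles(rep(train_mean[1], length(test_idx)),
                          rep(train_mean[2], length(test_idx)),
                          rep(train_mean[3], length(test_idx)))

  rows <- list(tibble(
    model = "baseline-mean",
    mae_per_angle = mae_pose(baseline, truth, "per-angle"),
    mae_l2 = mae_pose(baseline, truth, "l2")
  ))
  for (sc in c("uniform", "conv1x1", "variance")) {
    reg <- fit_pose_regressor(dataset, scoring = sc, seed = seed,
                              rasters = rasters, ...)
    pred <- predict(reg, rasters[test_idx])
    rows[[length(rows) + 1L]] <- tibble(
      model = sc,
      mae_per_angle = mae_pose(pred, truth, "per-angle"),
      mae_l2 = mae_pose(pred, truth, "l2")
    )
  }
  out <- dplyr::bind_rows(rows)
  out$n_train <- length(train_idx)
  out$n_test <- length(test_idx)
  class(out) <- c("scoring_comparison", class(out))
  out
}
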