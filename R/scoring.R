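# Pixelwise scoring functions for fine-grained feature aggregation.
#
# A feature map is an h x w grid of c-dimensional pixel-level features u,
# stored as a numeric array of dim c(h, w, c). A scoring function assigns
# each cell a scalar importance Phi(u):
#   * uniform:  Phi(u) = 1                 (no spatial preference)
#   * variance: Phi(u) = sum_i (u_i - mu)^2, mu = mean(u)
#   * conv1x1:  Phi(u) = sigmoid(w . u)    (learnable kernel w)
# Scored features are compressed by a score-weighted top-k mean, a documented
# simplified stand-in for capsule-style aggregation.

validate_feature_map <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3L || any(dim(f) < 1L) ||
      !all(is.finite(f))) {
    cp_abort("A feature map must be a finite array of dim (h, w, c).",
             "invalid_argument")
  }
  invisible(f)
}

#' Pixelwise scoring functions
#'
#' `score_uniform()` assigns every cell the constant 1; `score_variance()`
#' assigns the within-feature variance sum `sum((u - mean(u))^2)`;
#' `score_conv1x1()` assigns the sigmoid of the dot product with a learnable
#' kernel, `plogis(sum(w * u))`. All are pure and shape-preserving: an
#' `h x w x c` feature map yields an `h x w` score matrix.
#'
#' @param f Feature map array of dim `c(h, w, c)`.
#' @param w Numeric kernel of length `c` (for `score_conv1x1`).
#' @return An `h x w` numeric score matrix.
#' @examples
#' f <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
#' score_uniform(f)
#' score_variance(f)
#' score_conv1x1(f, c(1, 0, -1))
#' @export
score_uniform <- function(f) {
  validate_feature_map(f)
  matrix(1, dim(f)[1], dim(f)[2])
}

#' @rdname score_uniform
#' @export
score_variance <- function(f) {
  validate_feature_map(f)
  mu <- apply(f, c(1, 2), mean)
  apply(sweep(f, c(1, 2), mu)^2, c(1, 2), sum)
}

#' @rdname score_uniform
#' @export
score_conv1x1 <- function(f, w) {
  validate_feature_map(f)
  if (!is.numeric(w) || length(w) != dim(f)[3] || !all(is.finite(w))) {
    cp_abort("Kernel `w` must be finite and match the feature dimension.",
             "invalid_argument")
  }
  d <- dim(f)
  flat <- matrix(f, d[1] * d[2], d[3])  # cells x c
  matrix(plogis(as.numeric(flat %*% w)), d[1], d[2])
}

#' Score-weighted top-k feature aggregation
#'
#' Selects the `k` cells with the highest scores (ties broken by row-major
#' position: earlier rows, then earlier columns, win) and returns the
#' score-weighted mean of their feature vectors, with weights renormalized to
#' sum to 1 (equal weights when the selected scores sum to 0). The output
#' always lies in the convex hull of the selected feature vectors.
#'
#' @param f Feature map array of dim `c(h, w, c)`.
#' @param s Score matrix of dim `c(h, w)` (from a `score_*` function).
#' @param k Number of cells to select, in `1..h*w`.
#' @return A numeric feature vector of length `c`.
#' @export
aggregate_features <- function(f, s, k) {
  validate_feature_map(f)
  d <- dim(f)
  if (!is.matrix(s) || !all(dim(s) == d[1:2]) || !all(is.finite(s))) {
    cp_abort("Score matrix shape must match the feature map grid.",
             "invalid_argument")
  }
  if (length(k) != 1L || !is.finite(k) || k < 1 || k > d[1] * d[2]) {
    cp_abort("`k` must lie in 1..h*w.", "invalid_argument")
  }
  k <- as.integer(k)
  cells <- tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    score = as.numeric(s)
  )
  cells <- cells[order(-cells$score, cells$row, cells$col), ][seq_len(k), ]
  wts <- cells$score
  wts <- if (sum(wts) > 0) wts / sum(wts) else rep(1 / k, k)
  feats <- matrix(f, d[1] * d[2], d[3])[(cells$col - 1L) * d[1] + cells$row, ,
                                        drop = FALSE]
  as.numeric(crossprod(feats, wts))
}

#' Gradient-orientation histogram features of a raster
#'
#' Divides the raster into a fixed `grid[1] x grid[2]` cell grid and computes
#' a magnitude-weighted histogram of gradient orientations (`n_bins` signed
#' bins over `(-pi, pi]`, central differences) per cell — the pixel-level
#' feature map the toy pose regressor operates on.
#'
#' @param raster Numeric image matrix (rows = y, columns = x).
#' @param grid Cell grid `c(rows, cols)`.
#' @param n_bins Number of orientation bins.
#' @return A feature map array of dim `c(grid[1], grid[2], n_bins)`.
#' @export
extract_features <- function(raster, grid = c(6, 6), n_bins = 8) {
  stopifnot(is.matrix(raster), all(grid >= 1), n_bins >= 1)
  h <- nrow(raster)
  w <- ncol(raster)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (raster[, 3:w] - raster[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (raster[3:h, ] - raster[1:(h - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  bin <- pmin(n_bins, floor((ang + pi) / (2 * pi) * n_bins) + 1L)
  cell_r <- pmin(grid[1], floor((row(raster) - 1) / h * grid[1]) + 1L)
  cell_c <- pmin(grid[2], floor((col(raster) - 1) / w * grid[2]) + 1L)
  idx <- cell_r + (cell_c - 1L) * grid[1] +
    (bin - 1L) * grid[1] * grid[2]
  acc <- numeric(grid[1] * grid[2] * n_bins)
  sums <- tapply(as.numeric(mag), as.integer(idx), sum)
  acc[as.integer(names(sums))] <- sums
  array(acc, c(grid[1], grid[2], n_bins))
}
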