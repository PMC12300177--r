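# Independent oracles used by the test-suite. These deliberately take the
# slow, brute-force route so they share no code path with the package
# implementation they check.

# Pixel-enumeration IoU for integer-coordinate half-open boxes: count the
# integer pixels inside both boxes and inside either box.
pixel_iou_oracle <- function(a, b) {
  pix <- function(box) {
    if (box[3] <= box[1] || box[4] <= box[2]) return(character(0))
    g <- expand.grid(x = seq(box[1], box[3] - 1), y = seq(box[2], box[4] - 1))
    paste(g$x, g$y)
  }
  pa <- pix(a)
  pb <- pix(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# All-points interpolated AP via the per-true-positive identity:
# AP = (1/n_truth) * sum over TP ranks i of max_{j >= i} precision_j.
ap_oracle <- function(tp, n_truth) {
  if (length(tp) == 0) return(0)
  prec <- cumsum(tp) / seq_along(tp)
  sum(vapply(which(tp), function(i) max(prec[i:length(prec)]), numeric(1))) /
    n_truth
}

# Brute-force greedy-matching oracle for one image: walk predictions in
# descending score order; each takes the maximum-IoU unmatched truth and is a
# TP iff that IoU clears the threshold. Re-derived from the matching
# definition with scalar loops and no shared helpers.
match_oracle_one_image <- function(pred_boxes, pred_scores, truth_boxes,
                                   thresh = 0.5) {
  iou1 <- function(a, b) {
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) +
               (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  ord <- order(-pred_scores)
  used <- rep(FALSE, length(truth_boxes))
  tp <- logical(length(pred_scores))
  for (i in ord) {
    best <- -1
    best_j <- 0
    for (j in seq_along(truth_boxes)) {
      if (used[j]) next
      v <- iou1(pred_boxes[[i]], truth_boxes[[j]])
      if (v > best) {
        best <- v
        best_j <- j
      }
    }
    if (best_j > 0 && best >= thresh) {
      used[best_j] <- TRUE
      tp[i] <- TRUE
    }
  }
  tp
}

# Reprojection-minimizing pose oracle: direct nonlinear search over
# (yaw, pitch, roll, tx, ty, tz) minimizing the reprojection RMSE, started
# near the truth. Independent of the POSIT iteration.
pose_refine_oracle <- function(corr, scheme, cam, start) {
  obj <- function(p) {
    R <- rotation_from_angles(p[1], p[2], p[3])
    pr <- tryCatch(
      project_points(scheme$landmarks[match(corr$label, scheme$landmarks$label), ],
                     R, p[4:6], cam),
      error = function(e) NULL
    )
    if (is.null(pr)) return(1e9)
    mean((pr$x - corr$x)^2 + (pr$y - corr$y)^2)
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit$par
}

# Shared fixture: noiseless correspondences for a scheme at a known pose.
project_scheme <- function(scheme, yaw, pitch, roll, translation, cam) {
  R <- rotation_from_angles(yaw, pitch, roll)
  p2d <- project_points(scheme$landmarks, R, translation, cam)
  tibble::tibble(label = scheme$landmarks$label, x = p2d$x, y = p2d$y,
                 visible = TRUE)
}

max_angle_diff <- function(a, b) {
  d <- abs(as.matrix(a[, c("yaw_deg", "pitch_deg", "roll_deg")]) -
             as.matrix(b[, c("yaw_deg", "pitch_deg", "roll_deg")]))
  d <- pmin(d, 360 - d)  # compare as circular quantities
  max(d)
}
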