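# Detection and pose evaluation: box/mask IoU, greedy score-ordered matching
# with precision/recall at a fixed IoU threshold, all-points interpolated
# average precision, and the pose mean absolute error in degrees.
#
# Boxes are half-open pixel rectangles [x0, x1) x [y0, y1), so area and
# intersection arithmetic agree exactly with integer pixel enumeration.

validate_boxes <- function(b, name) {
  if (is.numeric(b) && length(b) == 4L) {
    b <- tibble(x0 = b[[1]], y0 = b[[2]], x1 = b[[3]], y1 = b[[4]])
  }
  if (!is.data.frame(b) || !all(c("x0", "y0", "x1", "y1") %in% names(b))) {
    cp_abort(sprintf("`%s` must be a box (x0, y0, x1, y1) or a data frame with those columns.",
                     name), "invalid_argument")
  }
  if (any(!is.finite(as.matrix(b[, c("x0", "y0", "x1", "y1")]))) ||
      any(b$x1 <= b$x0) || any(b$y1 <= b$y0)) {
    cp_abort(sprintf("`%s` contains an invalid box (need x1 > x0, y1 > y0).",
                     name), "invalid_argument")
  }
  b
}

#' Intersection over union of bounding boxes
#'
#' Boxes use the half-open convention `[x0, x1) x [y0, y1)`; IoU is the
#' intersection area divided by the union area, and 0 for disjoint boxes.
#' Vectorized row-wise when given data frames.
#'
#' @param a,b Boxes: length-4 numeric vectors `c(x0, y0, x1, y1)` or data
#'   frames with those columns (recycled row-wise to a common length).
#' @return Numeric IoU value(s) in `[0, 1]`.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 50 / 150
#' @export
box_iou <- function(a, b) {
  a <- validate_boxes(a, "a")
  b <- validate_boxes(b, "b")
  n <- max(nrow(a), nrow(b))
  a <- a[rep_len(seq_len(nrow(a)), n), ]
  b <- b[rep_len(seq_len(nrow(b)), n), ]
  iw <- pmax(0, pmin(a$x1, b$x1) - pmax(a$x0, b$x0))
  ih <- pmax(0, pmin(a$y1, b$y1) - pmax(a$y0, b$y0))
  inter <- iw * ih
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) +
    (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / union
}

#' Intersection over union of mask polygons
#'
#' Area-ratio IoU for simple polygons (used for segmentation-mask overlap);
#' the polygons are intersected by Sutherland-Hodgman clipping, so both must
#' be convex (the generator's mask polygons are convex hulls).
#'
#' @param a,b Polygons as k x 2 vertex matrices.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  area_a <- polygon_area(a)
  area_b <- polygon_area(b)
  if (area_a <= 0 || area_b <= 0) {
    cp_abort("Mask polygons must have positive area.", "invalid_argument")
  }
  inter <- polygon_area(clip_convex(a, b))
  inter / (area_a + area_b - inter)
}

polygon_area <- function(p) {
  if (is.null(p) || nrow(p) < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Sutherland-Hodgman: clip subject polygon against convex clip polygon.
clip_convex <- function(subject, clip) {
  # orient clip counter-clockwise (positive signed area)
  sa <- {
    x <- clip[, 1]; y <- clip[, 2]
    xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
    sum(x * ys - xs * y) / 2
  }
  if (sa < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  k <- nrow(clip)
  for (e in seq_len(k)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[e, ]
    b <- clip[if (e == k) 1L else e + 1L, ]
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    for (i in seq_len(m)) {
      cur <- inp[i, ]
      prv <- inp[if (i == 1) m else i - 1, ]
      sc <- side(cur); sp <- side(prv)
      if (sc >= 0) {
        if (sp < 0) out <- rbind(out, intersect_seg(prv, cur, a, b))
        out <- rbind(out, cur)
      } else if (sp >= 0) {
        out <- rbind(out, intersect_seg(prv, cur, a, b))
      }
    }
  }
  out
}

intersect_seg <- function(p, q, a, b) {
  d1 <- q - p; d2 <- b - a
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
  p + t * d1
}

#' Match detections to ground truth and score precision/recall/mAP
#'
#' Per image, predictions are processed in descending score order (greedy,
#' one-to-one): a prediction is a true positive iff its best-overlapping
#' still-unmatched ground-truth box has IoU at or above `iou_threshold`.
#' Precision is TP / (TP + FP), recall TP / (TP + FN). The mAP is the
#' all-points interpolated average precision over the pooled, score-ranked
#' detections (single class); in the one-object-one-prediction-per-image
#' regime it degenerates to precision at the fixed threshold.
#'
#' @param pred Predictions: tibble with `image_id`, `x0`, `y0`, `x1`, `y1`
#'   and optionally `score` in `[0, 1]` (required when an image has more
#'   than one prediction; defaults to 1).
#' @param truth Ground truth: tibble with `image_id`, `x0`, `y0`, `x1`, `y1`.
#' @param iou_threshold Minimum IoU for a correct detection.
#' @return An object of class `detection_eval` with `precision`, `recall`,
#'   `mAP`, the `matches` tibble, TP/FP/FN counts and a `degenerate` flag
#'   (TRUE when there were no predictions or no ground truths, in which case
#'   precision and recall are reported as 0 and `mAP` is `NA`).
#' @examples
#' truth <- tibble::tibble(image_id = "a", x0 = 0, y0 = 0, x1 = 10, y1 = 10)
#' pred <- tibble::tibble(image_id = "a", x0 = 1, y0 = 0, x1 = 11, y1 = 10,
#'                        score = 0.9)
#' glance(evaluate_detections(pred, truth))
#' @export
evaluate_detections <- function(pred, truth, iou_threshold = 0.5) {
  # normalize column-less empty inputs (e.g. from bind_rows(list()))
  empty_det <- tibble(image_id = character(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(), score = numeric())
  if (nrow(pred) == 0) pred <- empty_det
  if (nrow(truth) == 0) truth <- empty_det[, 1:5]
  if (!"score" %in% names(pred)) {
    if (any(duplicated(pred$image_id))) {
      cp_abort("`score` is required when an image has multiple predictions.",
               "invalid_argument")
    }
    pred$score <- rep(1, nrow(pred))
  }
  if (nrow(pred) > 0) {
    if (any(pred$score < 0 | pred$score > 1)) {
      cp_abort("Prediction scores must lie in [0, 1].", "invalid_argument")
    }
    validate_boxes(pred, "pred")
  }
  if (nrow(truth) > 0) validate_boxes(truth, "truth")

  degenerate <- nrow(pred) == 0 || nrow(truth) == 0
  matches <- list()
  pred$.pred_row <- seq_len(max(nrow(pred), 0L))
  for (img in unique(c(pred$image_id, truth$image_id))) {
    p <- pred[pred$image_id == img, ]
    tr <- truth[truth$image_id == img, ]
    p <- p[order(-p$score, p$.pred_row), ]
    matched <- rep(FALSE, nrow(tr))
    for (i in seq_len(nrow(p))) {
      best_iou <- -1
      best_j <- NA_integer_
      for (j in seq_len(nrow(tr))) {
        if (matched[j]) next
        v <- box_iou(p[i, ], tr[j, ])
        if (v > best_iou) {
          best_iou <- v
          best_j <- j
        }
      }
      tp <- !is.na(best_j) && best_iou >= iou_threshold
      if (tp) matched[best_j] <- TRUE
      matches[[length(matches) + 1L]] <- tibble(
        image_id = img,
        pred_row = p$.pred_row[i],
        truth_row = if (tp) best_j else NA_integer_,
        iou = if (!is.na(best_j)) best_iou else NA_real_,
        score = p$score[i],
        tp = tp
      )
    }
  }
  matches <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble(image_id = character(), pred_row = integer(),
           truth_row = integer(), iou = numeric(), score = numeric(),
           tp = logical())

  n_truth <- nrow(truth)
  tp <- sum(matches$tp)
  fp <- nrow(matches) - tp
  fn <- n_truth - tp
  precision <- if (nrow(matches) > 0) tp / (tp + fp) else 0
  recall <- if (n_truth > 0) tp / n_truth else 0
  mAP <- if (degenerate) NA_real_ else {
    ranked <- matches[order(-matches$score, matches$pred_row), ]
    average_precision(ranked$tp, n_truth)
  }
  structure(
    list(precision = precision, recall = recall, mAP = mAP,
         matches = matches, tp = tp, fp = fp, fn = fn,
         iou_threshold = iou_threshold, degenerate = degenerate),
    class = "detection_eval"
  )
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf(
    "<detection_eval> precision %.3f, recall %.3f, mAP %s (TP %d, FP %d, FN %d @ IoU %.2f)%s\n",
    x$precision, x$recall,
    if (is.na(x$mAP)) "NA" else sprintf("%.3f", x$mAP),
    x$tp, x$fp, x$fn, x$iou_threshold,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' @rdname evaluate_detections
#' @param x A `detection_eval`.
#' @param ... Unused.
#' @method tidy detection_eval
#' @export
tidy.detection_eval <- function(x, ...) {
  x$matches
}

#' @rdname evaluate_detections
#' @method glance detection_eval
#' @export
glance.detection_eval <- function(x, ...) {
  tibble(precision = x$precision, recall = x$recall, mAP = x$mAP,
         tp = x$tp, fp = x$fp, fn = x$fn,
         iou_threshold = x$iou_threshold, degenerate = x$degenerate)
}

#' All-points interpolated average precision
#'
#' Area under the precision envelope versus recall for a score-ranked list of
#' detection outcomes. With one object and one prediction per image this
#' reduces to precision at the fixed IoU threshold.
#'
#' @param tp Logical vector of true-positive flags, ordered by descending
#'   detection score.
#' @param n_truth Total number of ground-truth objects (> 0).
#' @return AP in `[0, 1]`.
#' @examples
#' average_precision(c(TRUE, FALSE, TRUE), 3)
#' @export
average_precision <- function(tp, n_truth) {
  if (length(n_truth) != 1L || !is.finite(n_truth) || n_truth <= 0) {
    cp_abort("AP is undefined without ground-truth objects.", "undefined_ap")
  }
  tp <- as.logical(tp)
  if (length(tp) == 0) return(0)
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_truth
  # precision envelope: best precision achievable at recall >= r
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Mean absolute error between predicted and true poses
#'
#' Differences are computed per angle and wrapped into `(-180, 180]` before
#' taking magnitudes, so e.g. predicted yaw 179 versus truth -179 contributes
#' a 2-degree error. Two norms are provided: `"per-angle"` (the head-pose
#' benchmark convention) averages `mean(|dyaw|, |dpitch|, |droll|)` over
#' images; `"l2"` averages the Euclidean norm of the wrapped difference
#' vector, `mean ||pred_n - truth_n||`.
#'
#' @param pred,truth Pose tibbles (`yaw_deg`, `pitch_deg`, `roll_deg`) of
#'   equal length (>= 1 row).
#' @param norm `"per-angle"` (default) or `"l2"`.
#' @return MAE in degrees.
#' @examples
#' mae_pose(pose_angles(3, 4, 0), pose_angles(0, 0, 0), norm = "l2")  # 5
#' @export
mae_pose <- function(pred, truth, norm = c("per-angle", "l2")) {
  norm <- match.arg(norm)
  cols <- c("yaw_deg", "pitch_deg", "roll_deg")
  if (!is.data.frame(pred) || !is.data.frame(truth) ||
      !all(cols %in% names(pred)) || !all(cols %in% names(truth))) {
    cp_abort("`pred` and `truth` must be pose tibbles (yaw_deg, pitch_deg, roll_deg).",
             "invalid_argument")
  }
  if (nrow(pred) != nrow(truth) || nrow(pred) < 1) {
    cp_abort("`pred` and `truth` must have equal, positive length.",
             "invalid_argument")
  }
  d <- as.matrix(pred[, cols]) - as.matrix(truth[, cols])
  d <- -wrap_deg(-d)  # wrapped into (-180, 180]
  if (norm == "per-angle") {
    mean(rowMeans(abs(d)))
  } else {
    mean(sqrt(rowSums(d^2)))
  }
}
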