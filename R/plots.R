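# ggplot2 autoplot methods for the package's result types.

#' Plot a synthetic sample
#'
#' Shows the projected landmarks (filled = visible), the convex-hull mask
#' polygon and the padded bounding box, in image coordinates (y axis
#' reversed, as on screen).
#'
#' @param object A `synthetic_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synthetic_sample
#' @export
autoplot.synthetic_sample <- function(object, ...) {
  lm <- object$landmarks
  hull <- as.data.frame(object$mask)
  names(hull) <- c("x", "y")
  bb <- as.list(object$bbox)
  ggplot2::ggplot(lm, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(data = hull, fill = "grey80", alpha = 0.5) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = bb$x0, xmax = bb$x1, ymin = bb$y0, ymax = bb$y1),
      inherit.aes = FALSE, fill = NA, colour = "steelblue",
      linetype = "dashed"
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$visible), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s (yaw %.1f, pitch %.1f, roll %.1f deg)",
                      object$sample_id, object$pose$yaw_deg,
                      object$pose$pitch_deg, object$pose$roll_deg),
      x = "x (px)", y = "y (px)", shape = "visible"
    )
}

#' Plot a detection evaluation as a precision-recall curve
#'
#' With one object and one prediction per image the curve degenerates to a
#' near-horizontal line (the single-object regime); the plot is mostly
#' useful for multi-object evaluations.
#'
#' @param object A `detection_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot detection_eval
#' @export
autoplot.detection_eval <- function(object, ...) {
  m <- object$matches
  m <- m[order(-m$score, m$pred_row), ]
  n_truth <- object$tp + object$fn
  df <- tibble(
    recall = cumsum(m$tp) / max(n_truth, 1),
    precision = cumsum(m$tp) / seq_len(nrow(m))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Precision-recall (AP = %s)",
                      if (is.na(object$mAP)) "NA" else
                        sprintf("%.3f", object$mAP)),
      x = "recall", y = "precision"
    )
}

#' Plot a scoring-variant comparison
#'
#' Bar chart of held-out MAE per scoring variant (and the mean-pose
#' baseline), per-angle and L2 norms side by side.
#'
#' @param object A [compare_scoring()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scoring_comparison
#' @export
autoplot.scoring_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("model", "mae_per_angle", "mae_l2")],
    cols = c("mae_per_angle", "mae_l2"),
    names_to = "norm", values_to = "mae"
  )
  df$norm <- ifelse(df$norm == "mae_per_angle", "per-angle", "L2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$mae,
                                   fill = .data$norm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "held-out MAE (deg)", fill = "norm",
                  title = "Scoring-variant comparison")
}
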