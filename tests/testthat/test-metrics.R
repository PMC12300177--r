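test_that("box IoU matches hand values and pixel enumeration", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150)
  withr::with_seed(17, {
    for (i in 1:100) {
      a <- c(sort(sample(0:40, 2)), sort(sample(0:40, 2)))[c(1, 3, 2, 4)]
      b <- c(sort(sample(0:40, 2)), sort(sample(0:40, 2)))[c(1, 3, 2, 4)]
      if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) next
      expect_equal(box_iou(a, b), pixel_iou_oracle(a, b))
    }
  })
  expect_error(box_iou(c(0, 0, 0, 10), c(0, 0, 1, 1)),
               class = "cowpose_error_invalid_argument")
})

test_that("IoU is symmetric and bounded", {
  withr::with_seed(29, {
    for (i in 1:50) {
      a <- runif(2, 0, 50)
      b <- runif(2, 0, 50)
      boxa <- c(a[1], a[2], a[1] + runif(1, 1, 30), a[2] + runif(1, 1, 30))
      boxb <- c(b[1], b[2], b[1] + runif(1, 1, 30), b[2] + runif(1, 1, 30))
      v1 <- box_iou(boxa, boxb)
      expect_equal(v1, box_iou(boxb, boxa))
      expect_gte(v1, 0)
      expect_lte(v1, 1)
    }
  })
})

test_that("mask IoU agrees with box IoU on rectangles", {
  rect_poly <- function(b) {
    cbind(c(b[1], b[3], b[3], b[1]), c(b[2], b[2], b[4], b[4]))
  }
  a <- c(0, 0, 10, 10)
  b <- c(5, 0, 15, 10)
  expect_equal(mask_iou(rect_poly(a), rect_poly(b)), box_iou(a, b))
  expect_equal(mask_iou(rect_poly(a), rect_poly(a)), 1)
  expect_equal(mask_iou(rect_poly(a), rect_poly(c(20, 20, 25, 25))), 0)
})

test_that("the five-truth three-detection worked example scores exactly", {
  truth <- tibble::tibble(
    image_id = "img", x0 = c(0, 20, 40, 60, 80), y0 = 0,
    x1 = c(10, 30, 50, 70, 90), y1 = 10
  )
  pred <- tibble::tibble(
    image_id = "img",
    x0 = c(1, 21, 200), y0 = 0, x1 = c(11, 31, 210), y1 = 10,
    score = c(0.9, 0.8, 0.7)
  )
  ev <- evaluate_detections(pred, truth, iou_threshold = 0.5)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 5)
  expect_equal(ev$tp, 2L)
})

test_that("perfect detections give precision = recall = AP = 1", {
  truth <- tibble::tibble(image_id = letters[1:4],
                          x0 = 0, y0 = 0, x1 = 10, y1 = 10)
  ev <- evaluate_detections(truth, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$mAP, 1)
})

test_that("precision/recall are invariant under image-order permutation", {
  withr::with_seed(41, {
    truth <- tibble::tibble(
      image_id = rep(letters[1:5], each = 2),
      x0 = runif(10, 0, 50), y0 = runif(10, 0, 50)
    )
    truth$x1 <- truth$x0 + runif(10, 5, 20)
    truth$y1 <- truth$y0 + runif(10, 5, 20)
    pred <- truth
    pred$x0 <- pred$x0 + rnorm(10, 0, 4)
    pred$x1 <- pred$x1 + rnorm(10, 0, 4)
    pred$score <- runif(10)
    ev1 <- evaluate_detections(pred, truth)
    perm <- sample(nrow(pred))
    ev2 <- evaluate_detections(pred[perm, ], truth[sample(nrow(truth)), ])
    expect_equal(ev1$precision, ev2$precision)
    expect_equal(ev1$recall, ev2$recall)
    expect_equal(ev1$mAP, ev2$mAP)
  })
})

test_that("matching agrees with the brute-force oracle on small scenarios", {
  withr::with_seed(53, {
    for (n_truth in 0:3) {
      for (n_pred in 0:3) {
        for (rep in 1:8) {
          if (n_truth == 0 && n_pred == 0) next
          mk <- function(n) {
            lapply(seq_len(n), function(i) {
              x0 <- runif(1, 0, 30)
              y0 <- runif(1, 0, 30)
              c(x0, y0, x0 + runif(1, 5, 20), y0 + runif(1, 5, 20))
            })
          }
          tb <- mk(n_truth)
          pb <- mk(n_pred)
          sc <- round(runif(n_pred), 3)
          truth <- dplyr::bind_rows(lapply(tb, function(b) {
            tibble::tibble(image_id = "i", x0 = b[1], y0 = b[2],
                           x1 = b[3], y1 = b[4])
          }))
          pred <- dplyr::bind_rows(lapply(seq_along(pb), function(i) {
            tibble::tibble(image_id = "i", x0 = pb[[i]][1], y0 = pb[[i]][2],
                           x1 = pb[[i]][3], y1 = pb[[i]][4], score = sc[i])
          }))
          if (n_truth == 0) truth <- truth[0, ]
          if (n_pred == 0) pred <- pred[0, ]
          ev <- evaluate_detections(pred, truth)
          oracle_tp <- if (n_pred > 0) {
            match_oracle_one_image(pb, sc, tb)
          } else {
            logical(0)
          }
          expect_equal(ev$tp, sum(oracle_tp))
          if (n_pred > 0 && n_truth > 0) {
            ranked <- oracle_tp[order(-sc)]
            expect_equal(ev$mAP, ap_oracle(ranked, n_truth))
          }
        }
      }
    }
  })
})

test_that("empty inputs yield the degenerate zero report", {
  empty <- tibble::tibble(image_id = character(), x0 = numeric(),
                          y0 = numeric(), x1 = numeric(), y1 = numeric())
  box <- tibble::tibble(image_id = "a", x0 = 0, y0 = 0, x1 = 5, y1 = 5)
  ev <- evaluate_detections(empty, box)
  expect_true(ev$degenerate)
  expect_equal(ev$precision, 0)
  expect_equal(ev$recall, 0)
  expect_true(is.na(ev$mAP))
})

test_that("average precision matches the direct PR-construction oracle", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE), 3), 1)
  expect_equal(average_precision(logical(0), 5), 0)
  flags <- c(TRUE, FALSE, TRUE)
  expect_equal(average_precision(flags, 3), ap_oracle(flags, 3))
  # single image, single TP prediction, one truth: degenerate AP = 1
  expect_equal(average_precision(TRUE, 1), 1)
  withr::with_seed(61, {
    for (i in 1:50) {
      n <- sample(1:8, 1)
      flags <- runif(n) < 0.5
      n_truth <- sum(flags) + sample(0:3, 1)
      if (n_truth == 0) n_truth <- 1
      expect_equal(average_precision(flags, n_truth),
                   ap_oracle(flags, n_truth))
    }
  })
  expect_error(average_precision(c(TRUE), 0),
               class = "cowpose_error_undefined_ap")
})

test_that("pose MAE handles both norms and wraps angle differences", {
  p <- pose_angles(3, 4, 0)
  z <- pose_angles(0, 0, 0)
  expect_equal(mae_pose(p, p), 0)
  expect_equal(mae_pose(p, z, norm = "l2"), 5)
  expect_equal(mae_pose(p, z, norm = "per-angle"), 7 / 3)
  expect_equal(mae_pose(pose_angles(179, 0, 0), pose_angles(-179, 0, 0)),
               2 / 3)
  expect_error(mae_pose(p, pose_angles(0:1, 0, 0)),
               class = "cowpose_error_invalid_argument")
  # both norms are >= 0 and 0 iff all wrapped differences vanish
  withr::with_seed(71, {
    a <- pose_angles(runif(20, -180, 179), runif(20, -90, 90),
                     runif(20, -180, 179))
    b <- pose_angles(runif(20, -180, 179), runif(20, -90, 90),
                     runif(20, -180, 179))
    expect_gt(mae_pose(a, b, "per-angle"), 0)
    expect_gt(mae_pose(a, b, "l2"), 0)
    expect_equal(mae_pose(a, a, "l2"), 0)
  })
})
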