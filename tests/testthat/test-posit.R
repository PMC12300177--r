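cam800 <- camera_model(800, c(640, 480))

test_that("identity pose is recovered to 1e-3 degrees and model units", {
  for (sch in list(head_scheme(), ear_scheme())) {
    corr <- project_scheme(sch, 0, 0, 0, c(0, 0, 10), cam800)
    fit <- solve_posit(corr, sch, cam800)
    a <- tidy(fit)
    expect_lt(max(abs(as.numeric(a))), 1e-3)
    expect_lt(max(abs(fit$translation - c(0, 0, 10))), 1e-3)
    expect_true(fit$converged)
    expect_gt(fit$translation[3], 0)
  }
})

test_that("noiseless random poses are recovered sharply (head scheme)", {
  sch <- head_scheme()
  withr::with_seed(101, {
    angle_errs <- rmses <- numeric(40)
    for (i in 1:40) {
      truth <- pose_angles(runif(1, -60, 60), runif(1, -60, 60),
                           runif(1, -60, 60))
      corr <- project_scheme(sch, truth$yaw_deg, truth$pitch_deg,
                             truth$roll_deg, c(0, 0, 10), cam800)
      fit <- solve_posit(corr, sch, cam800)
      angle_errs[i] <- max_angle_diff(tidy(fit), truth)
      rmses[i] <- fit$reprojection_rmse
    }
  })
  expect_lte(median(angle_errs), 0.5)
  expect_lt(median(rmses), 0.1)
})

test_that("POSIT agrees with a direct reprojection-minimizing oracle", {
  sch <- head_scheme()
  cam <- camera_model(500, c(400, 400))
  truth <- pose_angles(25, -15, 10)
  corr <- project_scheme(sch, 25, -15, 10, c(0.2, -0.1, 8), cam)
  fit <- solve_posit(corr, sch, cam)
  par <- pose_refine_oracle(corr, sch, cam, start = c(20, -10, 5, 0, 0, 7))
  expect_lt(max_angle_diff(tidy(fit), pose_angles(par[1], par[2], par[3])),
            0.05)
  expect_lt(max(abs(fit$translation - par[4:6])), 0.01)
})

test_that("reprojection RMSE is non-increasing across iterations (noiseless)", {
  sch <- head_scheme()
  withr::with_seed(55, {
    for (i in 1:10) {
      corr <- project_scheme(sch, runif(1, -50, 50), runif(1, -40, 40),
                             runif(1, -40, 40), c(0, 0, 10), cam800)
      tr <- solve_posit(corr, sch, cam800)$rmse_trace
      expect_true(all(diff(tr) <= 1e-6))
    }
  })
})

test_that("pose recovery is invariant to uniform model rescaling", {
  sch <- head_scheme()
  corr <- project_scheme(sch, 30, -20, 15, c(0, 0, 10), cam800)
  fit1 <- solve_posit(corr, sch, cam800)
  sch2 <- sch
  sch2$landmarks$x <- sch$landmarks$x * 3
  sch2$landmarks$y <- sch$landmarks$y * 3
  sch2$landmarks$z <- sch$landmarks$z * 3
  fit2 <- solve_posit(corr, sch2, cam800)
  expect_lt(max_angle_diff(tidy(fit1), tidy(fit2)), 1e-6)
  expect_equal(fit2$translation, 3 * fit1$translation, tolerance = 1e-6)
})

test_that("random landmark dropout keeps output invariants intact", {
  sch <- head_scheme()
  withr::with_seed(77, {
    for (i in 1:15) {
      corr <- project_scheme(sch, runif(1, -45, 45), runif(1, -30, 30),
                             runif(1, -30, 30), c(0, 0, 10), cam800)
      n_drop <- sample(0:(nrow(corr) - 4), 1)
      corr$visible[sample(nrow(corr), n_drop)] <- FALSE
      fit <- solve_posit(corr, sch, cam800)
      expect_gte(fit$reprojection_rmse, 0)
      expect_gte(fit$iterations, 1)
      expect_gt(fit$translation[3], 0)
      expect_lt(max(abs(crossprod(fit$rotation) - diag(3))), 1e-9)
    }
  })
})

test_that("accuracy degrades with landmark noise but stays bounded", {
  sch <- head_scheme()
  withr::with_seed(99, {
    errs0 <- errs2 <- numeric(25)
    for (i in 1:25) {
      truth <- pose_angles(runif(1, -60, 60), runif(1, -60, 60),
                           runif(1, -60, 60))
      corr <- project_scheme(sch, truth$yaw_deg, truth$pitch_deg,
                             truth$roll_deg, c(0, 0, 10), cam800)
      noisy <- corr
      noisy$x <- noisy$x + rnorm(nrow(corr), 0, 2)
      noisy$y <- noisy$y + rnorm(nrow(corr), 0, 2)
      errs0[i] <- max_angle_diff(estimate_pose(corr, sch, cam800), truth)
      errs2[i] <- max_angle_diff(estimate_pose(noisy, sch, cam800), truth)
    }
  })
  expect_lt(median(errs0), median(errs2))
  expect_lte(median(errs2), 5)
})

test_that("degenerate correspondence sets raise typed errors", {
  sch <- head_scheme()
  corr <- project_scheme(sch, 0, 0, 0, c(0, 0, 10), cam800)
  few <- corr[1:3, ]
  expect_error(solve_posit(few, sch, cam800),
               class = "cowpose_error_insufficient_landmarks")
  # a planar fake scheme must be rejected as degenerate
  flat <- head_scheme()
  flat$landmarks$z <- 0
  flat_corr <- corr
  expect_error(solve_posit(flat_corr, flat, cam800),
               class = "cowpose_error_degenerate_geometry")
  expect_error(solve_posit(corr[0, ], sch, cam800),
               class = "cowpose_error_insufficient_landmarks")
  bad <- corr
  bad$label[1] <- "No Such Landmark"
  expect_error(solve_posit(bad, sch, cam800),
               class = "cowpose_error_invalid_argument")
})
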