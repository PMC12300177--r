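cam_sim <- default_sim_camera()

test_that("zero-noise frontal sample keeps all head landmarks visible and exact", {
  sch <- head_scheme()
  s <- generate_sample(sch, pose_angles(0, 0, 0), c(0, 0, 4), cam_sim,
                       noise_config(0, 0, seed = 1))
  expect_true(all(s$landmarks$visible))
  exact <- project_points(sch$landmarks, diag(3), c(0, 0, 4), cam_sim)
  expect_equal(s$landmarks$x, exact$x)
  expect_equal(s$landmarks$y, exact$y)
})

test_that("samples are deterministic given the seed", {
  sch <- head_scheme()
  args <- list(sch, pose_angles(30, 10, -20), c(0, 0, 4), cam_sim,
               noise_config(1.5, 0.2, seed = 42))
  s1 <- do.call(generate_sample, args)
  s2 <- do.call(generate_sample, args)
  expect_identical(s1, s2)
})

test_that("bbox contains all visible landmarks and mask is a simple polygon", {
  sch <- head_scheme()
  withr::with_seed(5, {
    for (i in 1:10) {
      s <- generate_sample(sch,
                           pose_angles(runif(1, -80, 80), runif(1, -50, 50),
                                       runif(1, -50, 50)),
                           c(0, 0, 4), cam_sim,
                           noise_config(1, 0.1, seed = i))
      vis <- s$landmarks[s$landmarks$visible, ]
      expect_true(all(vis$x >= s$bbox["x0"] & vis$x <= s$bbox["x1"]))
      expect_true(all(vis$y >= s$bbox["y0"] & vis$y <= s$bbox["y1"]))
      # convex hulls are simple by construction; vertices must be unique
      expect_false(anyDuplicated(s$mask) > 0)
    }
  })
})

test_that("total dropout raises an empty-sample error", {
  expect_error(
    generate_sample(head_scheme(), pose_angles(0, 0, 0), c(0, 0, 4), cam_sim,
                    noise_config(0, 1, seed = 3)),
    class = "cowpose_error_empty_sample"
  )
})

test_that("dataset splits follow the rounding rule and partition records", {
  ds <- generate_dataset(1000, seed = 7)
  expect_equal(sum(ds$manifest$split == "train"), 600L)
  expect_equal(sum(ds$manifest$split == "val"), 200L)
  expect_equal(sum(ds$manifest$split == "test"), 200L)
  # singleton dataset goes entirely to train (remainder rule)
  d1 <- generate_dataset(1, seed = 7)
  expect_equal(d1$manifest$split, "train")
  # uneven n: round() for val/test, remainder to train
  d2 <- generate_dataset(7, split = c(train = 0.6, val = 0.2, test = 0.2),
                         seed = 7)
  expect_equal(sum(d2$manifest$split == "val"), round(7 * 0.2))
  expect_equal(sum(d2$manifest$split == "test"), round(7 * 0.2))
  expect_equal(sum(d2$manifest$split == "train"), 7 - 2 * round(7 * 0.2))
  expect_error(generate_dataset(10, split = c(0.5, 0.2, 0.2), seed = 1),
               class = "cowpose_error_invalid_argument")
})

test_that("same seed reproduces byte-identical manifests", {
  d1 <- generate_dataset(50, seed = 99)
  d2 <- generate_dataset(50, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_manifest(d1$manifest, f1)
  write_manifest(d2$manifest, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("rasterization places blobs at the landmarks", {
  # the ear scheme at a frontal pose gives well-separated blobs
  sch <- ear_scheme()
  s <- generate_sample(sch, pose_angles(0, 0, 0), c(0, 0, 4), cam_sim,
                       noise_config(0, 0, seed = 2))
  img <- rasterize_sample(s, cam_sim)
  expect_equal(dim(img), c(96, 96))
  vis <- s$landmarks[s$landmarks$visible, ]
  for (i in seq_len(nrow(vis))) {
    r <- ceiling(vis$y[i])
    c <- ceiling(vis$x[i])
    win <- img[(r - 3):(r + 3), (c - 3):(c + 3)]
    # the local maximum sits within one pixel of the landmark
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - 4)), 1)
    # blob intensity centroid reproduces the position within 0.5 px
    # (checked on interior landmarks, where the mask background is constant)
    if (grepl("Midline", vis$label[i])) {
      rows <- (r - 4):(r + 4)
      cols <- (c - 4):(c + 4)
      patch <- img[rows, cols] - min(img[rows, cols])
      cx <- sum(patch * rep(cols - 0.5, each = length(rows))) / sum(patch)
      cy <- sum(patch * rep(rows - 0.5, times = length(cols))) / sum(patch)
      expect_lt(abs(cx - vis$x[i]), 0.5)
      expect_lt(abs(cy - vis$y[i]), 0.5)
    }
  }
  # outside the padded bbox everything is black
  px <- matrix(rep(seq_len(96) - 0.5, each = 96), 96)
  py <- matrix(rep(seq_len(96) - 0.5, times = 96), 96)
  outside <- px < s$bbox["x0"] | px >= s$bbox["x1"] |
    py < s$bbox["y0"] | py >= s$bbox["y1"]
  expect_true(all(img[outside] == 0))
  # too few visible landmarks cannot be rasterized
  s3 <- s
  s3$landmarks$visible <- c(TRUE, TRUE, rep(FALSE, 11))
  expect_error(rasterize_sample(s3, cam_sim),
               class = "cowpose_error_cannot_rasterize")
})

test_that("generator and solver close the loop on zero-noise samples", {
  ds <- generate_dataset(15, pose_ranges = list(yaw = c(-60, 60),
                                                pitch = c(-40, 40),
                                                roll = c(-40, 40)),
                         seed = 31)
  sch <- head_scheme()
  for (s in ds$samples) {
    est <- estimate_pose(s$landmarks, sch, ds$cam)
    expect_lt(max_angle_diff(est, s$pose), 1e-3)
  }
})

test_that("datasets round-trip through the on-disk layout", {
  ds <- generate_dataset(6, seed = 13)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  back <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(back$sample_id, ds$manifest$sample_id)
  expect_equal(back$yaw_deg, ds$manifest$yaw_deg, tolerance = 1e-9)
  corr <- read_correspondences(file.path(dir, manifest$corr_file[1]))
  expect_equal(corr$label, head_scheme()$landmarks$label)
  expect_equal(corr$x, ds$samples[[1]]$landmarks$x, tolerance = 1e-9)
  via <- read_via_project(file.path(dir, "annotations_via.json"))
  expect_equal(nrow(via), 6L)
  expect_true(all(via$shape == "polygon"))
})
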