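# Synthetic scene generator: projects the canonical landmark schemes at known
# poses through a pinhole camera, with optional pixel noise and landmark
# dropout, and derives the detection ground truth (bounding box, mask polygon)
# that the evaluation machinery consumes. Fully deterministic given a seed.

#' Noise configuration for synthetic samples
#'
#' @param pixel_sigma Standard deviation (pixels) of isotropic Gaussian noise
#'   added to each projected landmark coordinate.
#' @param dropout_prob Probability that a landmark is dropped (simulating
#'   occlusion by the environment, on top of geometric self-occlusion).
#' @param seed Integer seed; identical configurations reproduce identical
#'   samples.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(pixel_sigma = 0, dropout_prob = 0, seed = 1L) {
  check_finite_scalar(pixel_sigma, "pixel_sigma")
  check_finite_scalar(dropout_prob, "dropout_prob")
  if (pixel_sigma < 0 || dropout_prob < 0 || dropout_prob > 1) {
    cp_abort("Need pixel_sigma >= 0 and dropout_prob in [0, 1].",
             "invalid_argument")
  }
  structure(
    list(pixel_sigma = pixel_sigma, dropout_prob = dropout_prob,
         seed = as.integer(seed)),
    class = "noise_config"
  )
}

#' Default camera used by the synthetic generator
#'
#' 96 x 96 pixel frame with a 192 px focal length: an object of unit extent at
#' the default depth of 4 model units fills roughly 60% of the frame and stays
#' inside it across the default pose ranges.
#'
#' @return A [camera_model()].
#' @export
default_sim_camera <- function() {
  camera_model(192, c(96, 96))
}

#' Generate one synthetic sample
#'
#' Projects every scheme landmark at the given pose, applies seeded pixel
#' noise and dropout, determines visibility (a landmark is visible when it is
#' not dropped and not self-occluded, i.e. its committed outward normal does
#' not face away from the camera), and derives the detection ground truth:
#' an axis-aligned bounding box around the visible landmarks padded by 5% per
#' side, and their convex hull as the mask polygon.
#'
#' @param scheme A `landmark_scheme`.
#' @param pose One-row pose tibble, or see [pose_angles()].
#' @param translation Length-3 translation in model units (z > 0).
#' @param cam A [camera_model()].
#' @param noise A [noise_config()].
#' @param sample_id Identifier stored on the sample.
#' @return An object of class `synthetic_sample`: `landmarks` tibble
#'   (`label`, `x`, `y`, `visible`), `pose`, `translation`, `bbox`
#'   (`c(x0, y0, x1, y1)`), `mask` (k x 2 polygon vertex matrix),
#'   `scheme_name`, `sample_id`.
#' @examples
#' s <- generate_sample(head_scheme(), pose_angles(20, -5, 3), c(0, 0, 4),
#'                      default_sim_camera(), noise_config(seed = 7))
#' s$bbox
#' @export
generate_sample <- function(scheme, pose, translation, cam,
                            noise = noise_config(), sample_id = "sample") {
  stopifnot(inherits(scheme, "landmark_scheme"), inherits(cam, "camera_model"),
            inherits(noise, "noise_config"))
  if (translation[3] <= 0) {
    cp_abort("Translation must put the object in front of the camera (z > 0).",
             "invalid_argument")
  }
  pose <- if (is.data.frame(pose)) {
    pose_angles(pose$yaw_deg, pose$pitch_deg, pose$roll_deg)
  } else {
    pose_angles(pose[1], pose[2], pose[3])
  }
  stopifnot(nrow(pose) == 1L)
  lm <- scheme$landmarks
  n <- nrow(lm)
  R <- rotation_from_angles(pose)
  p2d <- project_points(lm, R, translation, cam)

  Xc <- R %*% t(as.matrix(lm[, c("x", "y", "z")])) + translation
  Nw <- R %*% t(as.matrix(lm[, c("nx", "ny", "nz")]))
  self_occluded <- colSums(Nw * Xc) > 0

  withr::with_seed(noise$seed, {
    dropped <- runif(n) < noise$dropout_prob
    jitter <- matrix(rnorm(2 * n, 0, noise$pixel_sigma), n, 2)
  })
  x <- p2d$x + jitter[, 1]
  y <- p2d$y + jitter[, 2]
  visible <- !dropped & !self_occluded

  if (!any(visible)) {
    cp_abort("No landmark survived dropout/self-occlusion: empty sample.",
             "empty_sample")
  }

  vx <- x[visible]
  vy <- y[visible]
  pad_x <- max(0.05 * diff(range(vx)), 1)
  pad_y <- max(0.05 * diff(range(vy)), 1)
  bbox <- c(x0 = min(vx) - pad_x, y0 = min(vy) - pad_y,
            x1 = max(vx) + pad_x, y1 = max(vy) + pad_y)

  hull <- chull(vx, vy)
  mask <- cbind(x = vx[hull], y = vy[hull])

  structure(
    list(
      sample_id = sample_id,
      pose = pose,
      translation = as.numeric(translation),
      landmarks = tibble(label = lm$label, x = x, y = y, visible = visible),
      bbox = bbox,
      mask = mask,
      scheme_name = scheme$name
    ),
    class = "synthetic_sample"
  )
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf(
    "<synthetic_sample> '%s' (%s): %d/%d landmarks visible, yaw %.1f pitch %.1f roll %.1f deg\n",
    x$sample_id, x$scheme_name, sum(x$landmarks$visible),
    nrow(x$landmarks), x$pose$yaw_deg, x$pose$pitch_deg, x$pose$roll_deg
  ))
  invisible(x)
}

#' Generate a synthetic dataset with train/val/test splits
#'
#' Draws poses uniformly from `pose_ranges`, generates one sample per draw,
#' and assigns records to splits by a seeded shuffle. Split sizes are
#' `round(n * p)` for validation and test, with the remainder going to train,
#' so the default proportions reproduce a 60/20/20 partition exactly at
#' round numbers.
#'
#' @param n Number of samples (>= 1).
#' @param scheme A `landmark_scheme` (default the head scheme).
#' @param cam A [camera_model()].
#' @param pose_ranges Named list of `c(min, max)` degree ranges for `yaw`,
#'   `pitch`, `roll`.
#' @param translation Object translation (fixed across samples).
#' @param noise A [noise_config()]; its seed is re-derived per sample from
#'   `seed`.
#' @param split Named proportions `c(train, val, test)` summing to 1.
#' @param seed Master seed controlling poses, per-sample noise and the split
#'   shuffle.
#' @return An object of class `synthetic_dataset`: `manifest` tibble
#'   (`sample_id`, `split`, `yaw_deg`, `pitch_deg`, `roll_deg`), `samples`
#'   list, plus the generating `cam`, `scheme_name` and `seed`.
#' @examples
#' ds <- generate_dataset(50, seed = 1)
#' table(ds$manifest$split)
#' @export
generate_dataset <- function(n,
                             scheme = head_scheme(),
                             cam = default_sim_camera(),
                             pose_ranges = list(yaw = c(-90, 90),
                                                pitch = c(-60, 60),
                                                roll = c(-60, 60)),
                             translation = c(0, 0, 4),
                             noise = noise_config(),
                             split = c(train = 0.6, val = 0.2, test = 0.2),
                             seed = 1L) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    cp_abort("`n` must be a positive count.", "invalid_argument")
  }
  n <- as.integer(n)
  if (length(split) != 3L || any(split < 0) || abs(sum(split) - 1) > 1e-8) {
    cp_abort("`split` must be three non-negative proportions summing to 1.",
             "invalid_argument")
  }
  if (is.null(names(split))) names(split) <- c("train", "val", "test")

  withr::with_seed(as.integer(seed), {
    yaw <- runif(n, pose_ranges$yaw[1], pose_ranges$yaw[2])
    pitch <- runif(n, pose_ranges$pitch[1], pose_ranges$pitch[2])
    roll <- runif(n, pose_ranges$roll[1], pose_ranges$roll[2])
    sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
    shuffle <- sample.int(n)
  })

  n_val <- round(n * split[["val"]])
  n_test <- round(n * split[["test"]])
  n_train <- n - n_val - n_test
  split_lab <- character(n)
  split_lab[shuffle[seq_len(n_train)]] <- "train"
  if (n_val > 0) split_lab[shuffle[n_train + seq_len(n_val)]] <- "val"
  if (n_test > 0) split_lab[shuffle[n_train + n_val + seq_len(n_test)]] <- "test"

  ids <- sprintf("sample_%0*d", nchar(n), seq_len(n))
  samples <- purrr::map(seq_len(n), function(i) {
    ns <- noise_config(noise$pixel_sigma, noise$dropout_prob, sample_seeds[i])
    generate_sample(scheme, pose_angles(yaw[i], pitch[i], roll[i]),
                    translation, cam, ns, sample_id = ids[i])
  })

  manifest <- tibble(
    sample_id = ids,
    split = split_lab,
    yaw_deg = yaw,
    pitch_deg = pitch,
    roll_deg = roll
  )

  structure(
    list(manifest = manifest, samples = samples, cam = cam,
         scheme_name = scheme$name, seed = as.integer(seed)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  tab <- table(x$manifest$split)
  cat(sprintf("<synthetic_dataset> %d samples ('%s' scheme, seed %d): %s\n",
              nrow(x$manifest), x$scheme_name, x$seed,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Rasterize a synthetic sample to a grayscale image
#'
#' Renders the sample's mask polygon filled mid-gray on black, then adds one
#' isotropic Gaussian blob (sigma = 2 px) per visible landmark, each with a
#' distinct peak intensity so landmark identity is encoded in the image.
#' Pixels outside the sample's padded bounding box are forced to zero.
#' Deterministic.
#'
#' @param sample A `synthetic_sample` with at least 3 visible landmarks.
#' @param cam The [camera_model()] defining the raster size.
#' @return A numeric matrix of `image_size[2]` rows by `image_size[1]`
#'   columns; element `[r, c]` is the pixel whose centre is
#'   `(c - 0.5, r - 0.5)`.
#' @export
rasterize_sample <- function(sample, cam) {
  stopifnot(inherits(sample, "synthetic_sample"), inherits(cam, "camera_model"))
  vis <- sample$landmarks[sample$landmarks$visible, ]
  if (nrow(vis) < 3) {
    cp_abort("Rasterization needs at least 3 visible landmarks.",
             "cannot_rasterize")
  }
  w <- as.integer(cam$image_size[1])
  h <- as.integer(cam$image_size[2])
  px <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)   # pixel-centre x
  py <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)  # pixel-centre y

  img <- matrix(0, h, w)
  poly <- sample$mask
  k <- nrow(poly)
  if (k >= 3) {
    # convex polygon: a pixel is inside when every edge cross product has the
    # same sign (robust to either vertex orientation)
    inside_neg <- matrix(TRUE, h, w)
    inside_pos <- matrix(TRUE, h, w)
    for (e in seq_len(k)) {
      a <- poly[e, ]
      b <- poly[if (e == k) 1L else e + 1L, ]
      cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
      inside_neg <- inside_neg & (cr <= 0)
      inside_pos <- inside_pos & (cr >= 0)
    }
    img[inside_neg | inside_pos] <- 0.5
  }

  sigma <- 2
  n_all <- nrow(sample$landmarks)
  amp <- 0.3 + 0.7 * (seq_len(n_all) / n_all)
  vis_idx <- which(sample$landmarks$visible)
  for (ii in seq_along(vis_idx)) {
    i <- vis_idx[ii]
    cx <- sample$landmarks$x[i]
    cy <- sample$landmarks$y[i]
    cols <- max(1L, floor(cx - 4 * sigma)):min(w, ceiling(cx + 4 * sigma))
    rows <- max(1L, floor(cy - 4 * sigma)):min(h, ceiling(cy + 4 * sigma))
    if (length(cols) < 1 || length(rows) < 1) next
    dx2 <- ((cols - 0.5) - cx)^2
    dy2 <- ((rows - 0.5) - cy)^2
    img[rows, cols] <- img[rows, cols] +
      amp[i] * exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  }

  outside <- px < sample$bbox["x0"] | px >= sample$bbox["x1"] |
    py < sample$bbox["y0"] | py >= sample$bbox["y1"]
  img[outside] <- 0
  img
}

#' Extract detection ground truth from a dataset
#'
#' @param dataset A `synthetic_dataset`.
#' @return A tibble (`image_id`, `x0`, `y0`, `x1`, `y1`) of ground-truth
#'   boxes, one per sample.
#' @export
dataset_truth_boxes <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dplyr::bind_rows(purrr::map(dataset$samples, function(s) {
    tibble(image_id = s$sample_id,
           x0 = s$bbox[["x0"]], y0 = s$bbox[["y0"]],
           x1 = s$bbox[["x1"]], y1 = s$bbox[["y1"]])
  }))
}

#' Write a synthetic dataset to disk
#'
#' Emits `manifest.csv` (plus per-sample correspondence CSVs, a VIA project
#' JSON with the ground-truth mask polygons, and optional PNG rasters) in the
#' on-disk layout the command-line interface consumes.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @param rasters Write PNG rasters as well?
#' @return Invisibly, the manifest tibble augmented with file-path columns.
#' @export
write_dataset <- function(dataset, dir, rasters = FALSE) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "corr"), showWarnings = FALSE)
  if (rasters) dir.create(file.path(dir, "images"), showWarnings = FALSE)

  corr_files <- character(length(dataset$samples))
  image_files <- rep(NA_character_, length(dataset$samples))
  annos <- vector("list", length(dataset$samples))
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    corr_files[i] <- file.path("corr", paste0(s$sample_id, ".csv"))
    write_correspondences(s$landmarks, file.path(dir, corr_files[i]))
    annos[[i]] <- tibble(
      image_id = paste0(s$sample_id, ".png"),
      region_id = 1L,
      shape = "polygon",
      points = list(unname(s$mask)),
      x0 = NA_real_, y0 = NA_real_, x1 = NA_real_, y1 = NA_real_
    )
    if (rasters) {
      img <- rasterize_sample(s, dataset$cam)
      img <- pmin(pmax(img, 0), 1)
      image_files[i] <- file.path("images", paste0(s$sample_id, ".png"))
      png::writePNG(img, file.path(dir, image_files[i]))
    }
  }
  via_file <- "annotations_via.json"
  write_via_project(dplyr::bind_rows(annos), file.path(dir, via_file))

  manifest <- dataset$manifest
  manifest$corr_file <- corr_files
  manifest$via_file <- via_file
  manifest$image_file <- image_files
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
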