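# Rotation representations and the pinhole projection shared by the POSIT
# solver and the synthetic generator.
#
# Conventions, fixed package-wide:
#   * frame: x right, y down (image vertical), z forward; right-handed
#   * yaw   = rotation about the vertical axis (y)
#   * pitch = rotation about the side-to-side axis (x)
#   * roll  = rotation about the front-to-back axis (z)
#   * composition R = R_y(yaw) %*% R_x(pitch) %*% R_z(roll)
#     (intrinsic yaw-then-pitch-then-roll, the common head-pose convention)
#   * all public angles in degrees

deg2rad <- function(d) d * (pi / 180)
rad2deg <- function(r) r * (180 / pi)

# wrap into [-180, 180)
wrap_deg <- function(a) ((a + 180) %% 360) - 180

#' Construct a table of pose angles
#'
#' A pose is the 3D orientation of a head or ear, described by yaw (rotation
#' about the vertical axis, turning left/right), pitch (about the side-to-side
#' axis, nodding up/down) and roll (about the front-to-back axis, tilting).
#' Poses travel through the package as tibbles with columns `yaw_deg`,
#' `pitch_deg`, `roll_deg`, one row per image or sample.
#'
#' @param yaw,pitch,roll Numeric vectors of angles in degrees (recycled to a
#'   common length).
#' @return A tibble with columns `yaw_deg`, `pitch_deg`, `roll_deg`.
#' @examples
#' pose_angles(30, -10, 5)
#' @export
pose_angles <- function(yaw = 0, pitch = 0, roll = 0) {
  n <- max(length(yaw), length(pitch), length(roll))
  out <- tibble(
    yaw_deg   = rep_len(as.numeric(yaw), n),
    pitch_deg = rep_len(as.numeric(pitch), n),
    roll_deg  = rep_len(as.numeric(roll), n)
  )
  if (!all(is.finite(as.matrix(out)))) {
    cp_abort("Pose angles must be finite.", "invalid_argument")
  }
  out
}

# Accept either (yaw, pitch, roll) scalars or a one-row pose tibble.
as_pose_row <- function(yaw, pitch = NULL, roll = NULL) {
  if (is.data.frame(yaw)) {
    stopifnot(nrow(yaw) == 1L)
    c(yaw = yaw$yaw_deg, pitch = yaw$pitch_deg, roll = yaw$roll_deg)
  } else {
    check_finite_scalar(yaw, "yaw")
    check_finite_scalar(pitch, "pitch")
    check_finite_scalar(roll, "roll")
    c(yaw = yaw, pitch = pitch, roll = roll)
  }
}

#' Camera model (pinhole intrinsics)
#'
#' @param focal_length Focal length in pixels (> 0).
#' @param image_size Integer vector `c(width, height)` in pixels.
#' @param principal_point Optical centre `c(px, py)` in pixels; defaults to the
#'   image centre.
#' @return An object of class `camera_model`.
#' @examples
#' camera_model(800, c(640, 480))
#' @export
camera_model <- function(focal_length, image_size,
                         principal_point = image_size / 2) {
  check_finite_scalar(focal_length, "focal_length")
  if (focal_length <= 0) {
    cp_abort("`focal_length` must be positive.", "invalid_argument")
  }
  if (length(image_size) != 2L || any(!is.finite(image_size)) ||
      any(image_size <= 0)) {
    cp_abort("`image_size` must be two positive numbers (width, height).",
             "invalid_argument")
  }
  if (length(principal_point) != 2L || any(!is.finite(principal_point))) {
    cp_abort("`principal_point` must be two finite numbers.",
             "invalid_argument")
  }
  structure(
    list(
      focal_length = as.numeric(focal_length),
      image_size = as.numeric(image_size),
      principal_point = as.numeric(principal_point)
    ),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> f = %g px, image %g x %g px, principal point (%g, %g)\n",
    x$focal_length, x$image_size[1], x$image_size[2],
    x$principal_point[1], x$principal_point[2]
  ))
  invisible(x)
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix from yaw/pitch/roll
#'
#' Composes `R = R_y(yaw) %*% R_x(pitch) %*% R_z(roll)` in the package frame
#' (x right, y down, z forward, right-handed), angles in degrees.
#'
#' @param yaw Either the yaw angle in degrees, or a one-row pose tibble as
#'   returned by [pose_angles()].
#' @param pitch,roll Angles in degrees (ignored when `yaw` is a tibble).
#' @return A 3x3 proper orthonormal rotation matrix.
#' @examples
#' rotation_from_angles(90, 0, 0)
#' @export
rotation_from_angles <- function(yaw, pitch = 0, roll = 0) {
  a <- as_pose_row(yaw, pitch, roll)
  rot_y(deg2rad(a[["yaw"]])) %*%
    rot_x(deg2rad(a[["pitch"]])) %*%
    rot_z(deg2rad(a[["roll"]]))
}

# Orthonormality validation. Matrices produced by this package satisfy
# max|R'R - I| <= 1e-9; decomposition accepts up to 1e-6 so that matrices
# perturbed by downstream numerics still decompose, while genuinely broken
# inputs are rejected.
check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) {
    cp_abort("A rotation must be a finite 3x3 matrix.", "invalid_rotation")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    cp_abort("Matrix is not a proper rotation (orthonormal, det +1).",
             "invalid_rotation")
  }
  invisible(R)
}

#' Yaw/pitch/roll from a rotation matrix
#'
#' Decomposes a proper rotation under the package convention
#' `R = R_y(yaw) R_x(pitch) R_z(roll)`. The canonical ranges are
#' yaw, roll in `[-180, 180)` and pitch in `[-90, 90]`; at gimbal lock
#' (`|pitch| = 90`) roll is forced to 0 and yaw absorbs the free angle.
#'
#' @param R A 3x3 proper rotation matrix.
#' @return A one-row pose tibble (`yaw_deg`, `pitch_deg`, `roll_deg`).
#' @examples
#' angles_from_rotation(rotation_from_angles(30, -10, 5))
#' @export
angles_from_rotation <- function(R) {
  check_rotation(R)
  sp <- max(-1, min(1, -R[2, 3]))
  if (abs(R[2, 3]) >= 1 - 1e-9) {
    # gimbal: only yaw -/+ roll is observable; convention sets roll = 0
    pitch <- 90 * sign(sp)
    roll <- 0
    yaw <- if (sp > 0) {
      rad2deg(atan2(R[1, 2], R[1, 1]))
    } else {
      rad2deg(atan2(-R[1, 2], R[1, 1]))
    }
  } else {
    pitch <- rad2deg(asin(sp))
    yaw <- rad2deg(atan2(R[1, 3], R[3, 3]))
    roll <- rad2deg(atan2(R[2, 1], R[2, 2]))
  }
  pose_angles(wrap_deg(yaw), pitch, wrap_deg(roll))
}

#' Canonicalize pose angles
#'
#' Maps arbitrary finite angle triples to the canonical representation
#' (yaw, roll in `[-180, 180)`, pitch in `[-90, 90]`, roll = 0 at gimbal) by
#' composing to a rotation and decomposing again, so rows equivalent as
#' rotations map to the same triple.
#'
#' @param pose A pose tibble (`yaw_deg`, `pitch_deg`, `roll_deg`).
#' @return The canonicalized pose tibble, with attribute `wrapped`: a logical
#'   vector marking rows that changed by more than 1e-9 degrees.
#' @export
canonicalize_pose <- function(pose) {
  stopifnot(is.data.frame(pose))
  out <- purrr::map(seq_len(nrow(pose)), function(i) {
    angles_from_rotation(rotation_from_angles(pose[i, , drop = FALSE]))
  })
  out <- dplyr::bind_rows(out)
  wrapped <- rowSums(abs(as.matrix(out) -
    as.matrix(pose[, c("yaw_deg", "pitch_deg", "roll_deg")])) > 1e-9) > 0
  attr(out, "wrapped") <- wrapped
  out
}

#' Perspective projection of 3D model points
#'
#' Projects model points through `p = pp + f * ((R P + t)_xy / (R P + t)_z)`,
#' the standard pinhole model in the package frame (x right, y down,
#' z forward).
#'
#' @param points 3D points: an `n x 3` matrix or a data frame with columns
#'   `x`, `y`, `z` (model units).
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric translation (model units).
#' @param cam A [camera_model()].
#' @return A tibble with pixel columns `x`, `y`.
#' @examples
#' cam <- camera_model(100, c(200, 200), c(0, 0))
#' project_points(matrix(c(1, 0, 0), 1), diag(3), c(0, 0, 10), cam)
#' @export
project_points <- function(points, rotation, translation, cam) {
  P <- as_point_matrix(points)
  check_rotation(rotation)
  if (length(translation) != 3L || any(!is.finite(translation))) {
    cp_abort("`translation` must be three finite numbers.", "invalid_argument")
  }
  stopifnot(inherits(cam, "camera_model"))
  Xc <- rotation %*% t(P) + translation  # 3 x n, translation recycled by col
  if (any(Xc[3, ] <= 0)) {
    cp_abort("Point(s) behind the camera (z <= 0 after transform).",
             "behind_camera")
  }
  tibble(
    x = cam$principal_point[1] + cam$focal_length * Xc[1, ] / Xc[3, ],
    y = cam$principal_point[2] + cam$focal_length * Xc[2, ] / Xc[3, ]
  )
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  if (!is.matrix(points) || ncol(points) != 3L || !all(is.finite(points))) {
    cp_abort("`points` must be an n x 3 matrix of finite coordinates.",
             "invalid_argument")
  }
  points
}
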