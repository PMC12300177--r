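# POSIT: pose from orthography and scaling, with iterations.
#
# Classic iterative pose-from-correspondence. Starting from the scaled
# orthographic approximation (all perspective correction factors eps_i = 0),
# each iteration solves the linear pose equations through the pseudoinverse of
# the (centred) model-point matrix, orthonormalizes the two recovered pose
# rows into a proper rotation, and refreshes eps_i from the implied depths.
# Iteration stops when max |delta eps_i| drops below `tol`. At the fixed point
# the recovered pose satisfies the exact perspective equations, so noiseless
# correspondences are solved to numerical precision.

# Moore-Penrose pseudoinverse via SVD (rank-revealing; the solver has already
# rejected degenerate geometry, so all three singular values are used).
pinv <- function(A, rtol = 1e-12) {
  s <- svd(A)
  keep <- s$d > rtol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Nearest proper rotation (polar decomposition), tie-broken to det +1.
nearest_rotation <- function(M) {
  s <- svd(M)
  d <- det(s$u %*% t(s$v))
  s$u %*% diag(c(1, 1, sign(d))) %*% t(s$v)
}

validate_correspondences <- function(corr) {
  if (!is.data.frame(corr) || !all(c("label", "x", "y") %in% names(corr))) {
    cp_abort("Correspondences need columns label, x, y (and optional visible).",
             "invalid_argument")
  }
  if (!"visible" %in% names(corr)) corr$visible <- TRUE
  corr
}

#' Solve object pose from 2D-3D landmark correspondences (POSIT)
#'
#' Recovers the rotation and translation that map a landmark scheme's 3D
#' model points onto their annotated 2D image locations, using the classic
#' POSIT iteration. Only rows flagged visible participate; at least four
#' visible, non-coplanar landmarks are required.
#'
#' @param corr Correspondence tibble with columns `label`, `x`, `y` (pixels)
#'   and optionally `visible` (logical, default all `TRUE`). Labels must
#'   exist in `scheme`.
#' @param scheme A [head_scheme()], [ear_scheme()] or user scheme providing
#'   the 3D model points.
#' @param cam A [camera_model()].
#' @param tol Convergence threshold on the largest change of the perspective
#'   correction factors between iterations.
#' @param max_iter Iteration cap.
#' @return An object of class `posit_fit` with elements `rotation` (3x3),
#'   `translation` (length 3, z > 0), `iterations`, `converged`,
#'   `reprojection_rmse` (pixels), `rmse_trace` (per iteration), `n_visible`
#'   and the input metadata. Use [tidy()] for the recovered angles and
#'   [glance()] for the fit summary.
#' @examples
#' cam <- camera_model(800, c(640, 480))
#' sch <- head_scheme()
#' R <- rotation_from_angles(20, -10, 5)
#' p2d <- project_points(sch$landmarks, R, c(0, 0, 10), cam)
#' corr <- tibble::tibble(label = sch$landmarks$label, x = p2d$x, y = p2d$y)
#' fit <- solve_posit(corr, sch, cam)
#' tidy(fit)
#' @export
solve_posit <- function(corr, scheme, cam, tol = 1e-6, max_iter = 50L) {
  corr <- validate_correspondences(corr)
  stopifnot(inherits(scheme, "landmark_scheme"), inherits(cam, "camera_model"))
  lm <- scheme$landmarks
  missing_lab <- setdiff(corr$label, lm$label)
  if (length(missing_lab) > 0) {
    cp_abort(sprintf("Correspondence labels not in scheme '%s': %s",
                     scheme$name, paste(missing_lab, collapse = ", ")),
             "invalid_argument")
  }
  vis <- corr[corr$visible & is.finite(corr$x) & is.finite(corr$y), ]
  if (nrow(vis) < 4) {
    cp_abort(sprintf("POSIT needs at least 4 visible landmarks, got %d.",
                     nrow(vis)), "insufficient_landmarks")
  }
  idx <- match(vis$label, lm$label)
  P <- as.matrix(lm[idx, c("x", "y", "z")])
  sv <- svd(scale(P, scale = FALSE))$d
  if (sv[3] <= 1e-3 * sv[1]) {
    cp_abort("Visible landmarks are (near-)coplanar; POSIT is degenerate.",
             "degenerate_geometry")
  }

  f <- cam$focal_length
  u <- vis$x - cam$principal_point[1]
  v <- vis$y - cam$principal_point[2]
  n <- nrow(P)
  A <- sweep(P[-1, , drop = FALSE], 2, P[1, ])  # vectors M0 -> Mi
  B <- pinv(A)

  eps <- rep(0, n - 1)
  R <- diag(3)
  tvec <- c(0, 0, 1)
  rmse_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    xs <- u[-1] * (1 + eps) - u[1]
    ys <- v[-1] * (1 + eps) - v[1]
    I <- as.numeric(B %*% xs)
    J <- as.numeric(B %*% ys)
    s1 <- sqrt(sum(I^2))
    s2 <- sqrt(sum(J^2))
    if (!is.finite(s1) || !is.finite(s2) || s1 <= 0 || s2 <= 0) {
      cp_abort("POSIT linear system collapsed (zero scale).",
               "degenerate_geometry")
    }
    s <- sqrt(s1 * s2)
    R <- nearest_rotation(rbind(I / s1, J / s2, cross3(I / s1, J / s2)))
    Z0 <- f / s
    # camera position of the reference landmark; re-expressed for the model
    # origin so that X_cam = R P + t for every model point P
    t_ref <- c(u[1] * Z0 / f, v[1] * Z0 / f, Z0)
    tvec <- t_ref - as.numeric(R %*% P[1, ])
    eps_new <- as.numeric(A %*% R[3, ]) / Z0
    if (max(abs(eps_new)) > 10) {
      cp_abort("POSIT diverged (perspective corrections exploded).",
               "non_convergence")
    }
    rmse_trace <- c(rmse_trace, reprojection_rmse(P, R, tvec, cam, vis$x, vis$y))
    delta <- max(abs(eps_new - eps))
    eps <- eps_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  structure(
    list(
      rotation = R,
      translation = tvec,
      iterations = iter,
      converged = converged,
      reprojection_rmse = reprojection_rmse(P, R, tvec, cam, vis$x, vis$y),
      rmse_trace = rmse_trace,
      n_visible = n,
      scheme_name = scheme$name,
      cam = cam,
      correspondences = vis
    ),
    class = "posit_fit"
  )
}

reprojection_rmse <- function(P, R, tvec, cam, x_obs, y_obs) {
  Xc <- R %*% t(P) + tvec
  if (any(Xc[3, ] <= 0)) return(Inf)
  px <- cam$principal_point[1] + cam$focal_length * Xc[1, ] / Xc[3, ]
  py <- cam$principal_point[2] + cam$focal_length * Xc[2, ] / Xc[3, ]
  sqrt(mean((px - x_obs)^2 + (py - y_obs)^2))
}

#' @export
print.posit_fit <- function(x, ...) {
  a <- angles_from_rotation(x$rotation)
  cat(sprintf(
    paste0("<posit_fit> yaw %.2f, pitch %.2f, roll %.2f deg | ",
           "%d landmarks, %d iterations (%s), RMSE %.4g px\n"),
    a$yaw_deg, a$pitch_deg, a$roll_deg, x$n_visible, x$iterations,
    if (x$converged) "converged" else "not converged", x$reprojection_rmse
  ))
  invisible(x)
}

#' @rdname solve_posit
#' @param x A `posit_fit`.
#' @param ... Unused.
#' @method tidy posit_fit
#' @export
tidy.posit_fit <- function(x, ...) {
  angles_from_rotation(x$rotation)
}

#' @rdname solve_posit
#' @method glance posit_fit
#' @export
glance.posit_fit <- function(x, ...) {
  tibble(
    n_visible = x$n_visible,
    iterations = x$iterations,
    converged = x$converged,
    reprojection_rmse = x$reprojection_rmse,
    tz = x$translation[3]
  )
}

#' Estimate yaw/pitch/roll from landmark correspondences
#'
#' Convenience wrapper: [solve_posit()] followed by [angles_from_rotation()].
#'
#' @inheritParams solve_posit
#' @param ... Passed to [solve_posit()].
#' @return A one-row pose tibble (`yaw_deg`, `pitch_deg`, `roll_deg`).
#' @export
estimate_pose <- function(corr, scheme, cam, ...) {
  angles_from_rotation(solve_posit(corr, scheme, cam, ...)$rotation)
}
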