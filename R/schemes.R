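# Landmark scheme registry: the 21-point cattle-head scheme (with its mapping
# from the 21 AFLW human-face landmarks) and the 13-point left-ear scheme.
#
# The original 3D models the schemes were digitized from are not published, so
# the canonical coordinates committed here are authored, stylized stand-ins:
# a bovine head with landmarks on an ellipsoid-plus-muzzle form, and an ear as
# a curved paraboloid patch. Units are dimensionless model units with head
# (resp. ear) length = 1 and the origin at the landmark centroid. The pose
# solver recovers scale jointly, so units affect only translation, never
# angles. The muzzle points toward -z: at the identity pose the head faces
# the camera.
#
# Each landmark also carries a committed outward unit normal (nx, ny, nz),
# used by the synthetic generator's self-occlusion rule. Head normals point
# away from a pole behind the head so that every landmark is visible at the
# frontal pose; ear normals are the surface normals of the patch, facing the
# camera at identity.

head_landmark_table <- function() {
  # label, x (right +), y (down +), z (forward +; muzzle at -z)
  raw <- tibble::tribble(
    ~label,                                  ~x,    ~y,    ~z,
    "Left Upper Mandible",                  -0.38, -0.05,  0.15,
    "Left Eye Left Corner",                 -0.34, -0.18, -0.05,
    "Left Eye Right Corner",                -0.20, -0.16, -0.12,
    "Right Eye Left Corner",                 0.20, -0.16, -0.12,
    "Right Eye Right Corner",                0.34, -0.18, -0.05,
    "Right Upper Mandible",                  0.38, -0.05,  0.15,
    "Left Lower Mandible",                  -0.36,  0.10,  0.10,
    "Left Eye Right Lower Corner (medial)", -0.21, -0.08, -0.13,
    "Left Eye Right Lower Corner (lateral)",-0.30, -0.09, -0.07,
    "Right Eye Left Lower Corner",           0.21, -0.08, -0.13,
    "Right Eye Right Lower Corner",          0.30, -0.09, -0.07,
    "Right Lower Mandible",                  0.36,  0.10,  0.10,
    "Nose Left",                            -0.10,  0.18, -0.48,
    "Nose Center",                           0.00,  0.15, -0.52,
    "Nose Right",                            0.10,  0.18, -0.48,
    "Mouth Left Corner",                    -0.09,  0.32, -0.42,
    "Mouth Center",                          0.00,  0.35, -0.46,
    "Mouth Right Corner",                    0.09,  0.32, -0.42,
    "Left Ear Root",                        -0.30, -0.28,  0.28,
    "Right Ear Root",                        0.30, -0.28,  0.28,
    "Jaw",                                   0.00,  0.40, -0.30
  )
  # scale so head length (z extent) is exactly 1, then centre at the centroid
  scale <- 1 / diff(range(raw$z))
  raw$x <- raw$x * scale
  raw$y <- raw$y * scale
  raw$z <- raw$z * scale
  raw$x <- raw$x - mean(raw$x)
  raw$y <- raw$y - mean(raw$y)
  raw$z <- raw$z - mean(raw$z)
  # outward normals: away from a pole behind the head on the muzzle axis
  pole <- c(0, 0, max(raw$z) + 0.25)
  nrm <- cbind(raw$x - pole[1], raw$y - pole[2], raw$z - pole[3])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  raw$nx <- nrm[, 1]
  raw$ny <- nrm[, 2]
  raw$nz <- nrm[, 3]
  raw
}

head_symmetry_pairs <- function() {
  tibble::tribble(
    ~left,                                   ~right,
    "Left Upper Mandible",                   "Right Upper Mandible",
    "Left Eye Left Corner",                  "Right Eye Right Corner",
    "Left Eye Right Corner",                 "Right Eye Left Corner",
    "Left Eye Right Lower Corner (medial)",  "Right Eye Left Lower Corner",
    "Left Eye Right Lower Corner (lateral)", "Right Eye Right Lower Corner",
    "Left Lower Mandible",                   "Right Lower Mandible",
    "Nose Left",                             "Nose Right",
    "Mouth Left Corner",                     "Mouth Right Corner",
    "Left Ear Root",                         "Right Ear Root"
  )
}

ear_landmark_table <- function() {
  # 13 points apex -> base on a curved patch; ear length 1 along y,
  # depth curvature z = 0.8 x^2 + 0.4 y^2 (concave side toward the camera)
  grid <- tibble::tribble(
    ~label,               ~x,    ~y,
    "Apex",                0.00, -0.50,
    "Upper Medial Edge",  -0.15, -0.25,
    "Upper Midline",       0.00, -0.25,
    "Upper Lateral Edge",  0.15, -0.25,
    "Mid Medial Edge",    -0.20,  0.00,
    "Mid Midline",         0.00,  0.00,
    "Mid Lateral Edge",    0.20,  0.00,
    "Lower Medial Edge",  -0.15,  0.25,
    "Lower Midline",       0.00,  0.25,
    "Lower Lateral Edge",  0.15,  0.25,
    "Base Medial",        -0.10,  0.50,
    "Base Center",         0.00,  0.50,
    "Base Lateral",        0.10,  0.50
  )
  grid$z <- 0.8 * grid$x^2 + 0.4 * grid$y^2
  # surface normal of z - 0.8x^2 - 0.4y^2 = 0, oriented toward -z (camera)
  nrm <- cbind(1.6 * grid$x, 0.8 * grid$y, -1)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  grid$x <- grid$x - mean(grid$x)
  grid$y <- grid$y - mean(grid$y)
  grid$z <- grid$z - mean(grid$z)
  grid$nx <- nrm[, 1]
  grid$ny <- nrm[, 2]
  grid$nz <- nrm[, 3]
  grid
}

new_landmark_scheme <- function(name, landmarks, symmetry_pairs) {
  scheme <- structure(
    list(name = name, landmarks = landmarks, symmetry_pairs = symmetry_pairs),
    class = "landmark_scheme"
  )
  validate_scheme(scheme)
  scheme
}

validate_scheme <- function(scheme) {
  lm <- scheme$landmarks
  if (anyDuplicated(lm$label)) {
    cp_abort("Scheme labels must be unique.", "invalid_argument")
  }
  needed <- c("label", "x", "y", "z", "nx", "ny", "nz")
  if (!all(needed %in% names(lm))) {
    cp_abort("Scheme landmarks need columns label, x, y, z, nx, ny, nz.",
             "invalid_argument")
  }
  P <- as.matrix(lm[, c("x", "y", "z")])
  sv <- svd(scale(P, scale = FALSE))$d
  if (sv[3] <= 1e-3 * sv[1]) {
    cp_abort("Scheme canonical points are (near-)coplanar.",
             "degenerate_geometry")
  }
  sp <- scheme$symmetry_pairs
  if (nrow(sp) > 0) {
    bad <- !(sp$left %in% lm$label) | !(sp$right %in% lm$label)
    if (any(bad)) {
      cp_abort("Symmetry pair labels must be scheme labels.",
               "invalid_argument")
    }
  }
  invisible(scheme)
}

#' The 21-point cattle-head landmark scheme
#'
#' Twenty-one anatomical landmarks on the cattle head — mandible points, four
#' points around each eye, three across the external nose, the ear-root
#' attachments, three along the mouth, and the lowest point of the jaw —
#' mirroring the 21-landmark layout of the AFLW human-face scheme (see
#' [aflw_mapping()]). Coordinates are committed stylized model coordinates
#' (unit head length, centroid origin, muzzle toward -z); the scheme is
#' bilaterally symmetric across the x = 0 plane.
#'
#' Two eye landmarks whose published names collide are disambiguated as
#' "Left Eye Right Lower Corner (medial)" and "... (lateral)".
#'
#' @return A `landmark_scheme`: list with `name`, a `landmarks` tibble
#'   (`label`, `x`, `y`, `z`, outward normal `nx`, `ny`, `nz`) and a
#'   `symmetry_pairs` tibble (`left`, `right`).
#' @examples
#' head_scheme()
#' @export
head_scheme <- function() {
  new_landmark_scheme("head", head_landmark_table(), head_symmetry_pairs())
}

#' The 13-point cattle left-ear landmark scheme
#'
#' Thirteen landmarks evenly distributed from the apex to the base of the left
#' pinna, placed on a curved (non-planar) patch so that pose recovery from
#' correspondences is well-posed. Unit ear length, centroid origin.
#'
#' @return A `landmark_scheme`; the first label is the apex, the last a base
#'   landmark.
#' @examples
#' ear_scheme()
#' @export
ear_scheme <- function() {
  new_landmark_scheme(
    "ear", ear_landmark_table(),
    tibble(left = character(), right = character())
  )
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat(sprintf("<landmark_scheme> '%s': %d landmarks, %d symmetry pairs\n",
              x$name, nrow(x$landmarks), nrow(x$symmetry_pairs)))
  print(x$landmarks, n = 5)
  invisible(x)
}

#' Mapping from AFLW human-face landmarks to the cattle-head scheme
#'
#' The cattle-head scheme reuses the 21-landmark layout of the AFLW
#' (Annotated Facial Landmarks in the Wild) human-face scheme. Seven
#' landmarks map one-to-one (nose, mouth, chin/jaw); the rest are assigned
#' to the closest anatomical analog on the cattle head.
#'
#' @return A tibble with columns `aflw_label`, `cow_label` and `mapping_type`
#'   (`"one-to-one"` or `"closest-analog"`), 21 rows in AFLW order.
#' @examples
#' aflw_mapping()
#' @export
aflw_mapping <- function() {
  tibble::tribble(
    ~aflw_label,             ~cow_label,                              ~mapping_type,
    "Left Brow Left Corner",  "Left Upper Mandible",                  "closest-analog",
    "Left Brow Center",       "Left Eye Left Corner",                 "closest-analog",
    "Left Brow Right Corner", "Left Eye Right Corner",                "closest-analog",
    "Right Brow Left Corner", "Right Eye Left Corner",                "closest-analog",
    "Right Brow Center",      "Right Eye Right Corner",               "closest-analog",
    "Right Brow Right Corner","Right Upper Mandible",                 "closest-analog",
    "Left Eye Left Corner",   "Left Lower Mandible",                  "closest-analog",
    "Left Eye Center",        "Left Eye Right Lower Corner (medial)", "closest-analog",
    "Left Eye Right Corner",  "Left Eye Right Lower Corner (lateral)","closest-analog",
    "Right Eye Left Corner",  "Right Eye Left Lower Corner",          "closest-analog",
    "Right Eye Center",       "Right Eye Right Lower Corner",         "closest-analog",
    "Right Eye Right Corner", "Right Lower Mandible",                 "closest-analog",
    "Nose Left",              "Nose Left",                            "one-to-one",
    "Nose Center",            "Nose Center",                          "one-to-one",
    "Nose Right",             "Nose Right",                           "one-to-one",
    "Mouth Left Corner",      "Mouth Left Corner",                    "one-to-one",
    "Mouth Center",           "Mouth Center",                         "one-to-one",
    "Mouth Right Corner",     "Mouth Right Corner",                   "one-to-one",
    "Left Ear Lobe",          "Left Ear Root",                        "closest-analog",
    "Right Ear Lobe",         "Right Ear Root",                       "closest-analog",
    "Chin Center",            "Jaw",                                  "one-to-one"
  )
}

#' Export / import a landmark scheme as JSON
#'
#' Schemes serialize to a small JSON document (labels, coordinates, normals,
#' symmetry pairs) so users can substitute their own digitized 3D models.
#'
#' @param scheme A `landmark_scheme`.
#' @param path File path; for `write_scheme_json`, `NULL` returns the JSON
#'   text instead of writing.
#' @return `write_scheme_json` returns the JSON string (invisibly when
#'   writing); `read_scheme_json` returns a validated `landmark_scheme`.
#' @export
write_scheme_json <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "landmark_scheme"))
  doc <- list(
    name = scheme$name,
    landmarks = scheme$landmarks,
    symmetry_pairs = scheme$symmetry_pairs
  )
  txt <- jsonlite::toJSON(doc, dataframe = "columns", auto_unbox = TRUE,
                          digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) cp_abort(paste0("Malformed scheme JSON: ",
                                        conditionMessage(e)), "parse")
  )
  sp <- as_tibble(doc$symmetry_pairs)
  if (nrow(sp) == 0) sp <- tibble(left = character(), right = character())
  new_landmark_scheme(doc$name, as_tibble(doc$landmarks), sp)
}

#' Look up a scheme by name
#'
#' @param name `"head"` or `"ear"`.
#' @return A `landmark_scheme`.
#' @export
get_scheme <- function(name) {
  switch(name,
    head = head_scheme(),
    ear = ear_scheme(),
    cp_abort(sprintf("Unknown scheme '%s' (expected 'head' or 'ear').", name),
             "invalid_argument")
  )
}
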