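# Readers and writers for the annotation formats the toolkit touches:
# VIA (VGG Image Annotator) 2.x project JSON with polygon/rect regions,
# correspondence CSVs, pose-record CSVs and dataset manifests.
#
# Annotations travel as a tidy tibble with one row per region:
#   image_id, region_id, shape ("polygon"/"rect"), points (list column of
#   k x 2 matrices, polygons only), x0/y0/x1/y1 (rects only, half-open box).
# Only polygon and rect are supported; other VIA shapes are rejected loudly.

empty_via_tbl <- function() {
  tibble(image_id = character(), region_id = integer(), shape = character(),
         points = list(), x0 = numeric(), y0 = numeric(),
         x1 = numeric(), y1 = numeric())
}

#' Read a VIA 2.x project JSON
#'
#' Accepts both a full VIA project (with `_via_img_metadata`) and the flat
#' region-data export keyed by `filename + size`. Polygon regions must have
#' at least 3 vertices; rect regions are converted to half-open bounding
#' boxes and must have positive width and height. Any other region shape
#' raises an unsupported-shape error naming the shape.
#'
#' @param x Path to a JSON file, or a JSON string.
#' @return A region tibble (see file header), zero rows for an empty project.
#' @export
read_via_project <- function(x) {
  doc <- tryCatch(
    jsonlite::fromJSON(x, simplifyVector = FALSE),
    error = function(e) {
      cp_abort(paste0("Malformed VIA JSON: ", conditionMessage(e)), "parse")
    }
  )
  imgs <- doc[["_via_img_metadata"]] %||% doc
  # drop non-image bookkeeping keys of full project files
  imgs <- imgs[!grepl("^_via_", names(imgs) %||% character())]
  if (length(imgs) == 0) return(empty_via_tbl())

  rows <- list()
  for (entry in imgs) {
    fname <- entry$filename
    regions <- entry$regions %||% list()
    rid <- 0L
    for (reg in regions) {
      rid <- rid + 1L
      sa <- reg$shape_attributes
      shape <- sa$name
      if (identical(shape, "polygon")) {
        xs <- as.numeric(unlist(sa$all_points_x))
        ys <- as.numeric(unlist(sa$all_points_y))
        if (length(xs) < 3 || length(xs) != length(ys)) {
          cp_abort(sprintf("Polygon region in '%s' needs >= 3 (x, y) vertices.",
                           fname), "invalid_argument")
        }
        rows[[length(rows) + 1L]] <- tibble(
          image_id = fname, region_id = rid, shape = "polygon",
          points = list(matrix(c(xs, ys), ncol = 2)),
          x0 = NA_real_, y0 = NA_real_, x1 = NA_real_, y1 = NA_real_
        )
      } else if (identical(shape, "rect")) {
        if (sa$width <= 0 || sa$height <= 0) {
          cp_abort(sprintf("Rect region in '%s' needs positive width/height.",
                           fname), "invalid_argument")
        }
        rows[[length(rows) + 1L]] <- tibble(
          image_id = fname, region_id = rid, shape = "rect",
          points = list(NULL),
          x0 = as.numeric(sa$x), y0 = as.numeric(sa$y),
          x1 = as.numeric(sa$x + sa$width), y1 = as.numeric(sa$y + sa$height)
        )
      } else {
        cp_abort(sprintf("Unsupported VIA region shape '%s' in '%s'.",
                         shape %||% "<missing>", fname), "unsupported_shape")
      }
    }
  }
  if (length(rows) == 0) return(empty_via_tbl())
  dplyr::bind_rows(rows)
}

#' Write a VIA region tibble as project JSON
#'
#' Emits the flat VIA 2.x region-data dialect (entries keyed by
#' `filename + size`, size recorded as -1 when unknown) with deterministic
#' key ordering, so identical inputs produce byte-identical output.
#' `read_via_project()` of the output reproduces the input tibble.
#'
#' @param annotations A region tibble as returned by [read_via_project()].
#' @param path Output file; `NULL` returns the JSON text.
#' @return The JSON string, invisibly when writing to a file.
#' @export
write_via_project <- function(annotations, path = NULL) {
  if (nrow(annotations) == 0) {
    txt <- "{}"
  } else {
    entries <- list()
    for (img in unique(annotations$image_id)) {
      sub <- annotations[annotations$image_id == img, ]
      regions <- purrr::map(seq_len(nrow(sub)), function(i) {
        if (sub$shape[i] == "polygon") {
          pts <- sub$points[[i]]
          list(
            shape_attributes = list(
              name = "polygon",
              all_points_x = as.numeric(pts[, 1]),
              all_points_y = as.numeric(pts[, 2])
            ),
            region_attributes = stats::setNames(list(), character())
          )
        } else {
          list(
            shape_attributes = list(
              name = "rect",
              x = sub$x0[i], y = sub$y0[i],
              width = sub$x1[i] - sub$x0[i],
              height = sub$y1[i] - sub$y0[i]
            ),
            region_attributes = stats::setNames(list(), character())
          )
        }
      })
      entries[[paste0(img, "-1")]] <- list(
        filename = img, size = -1L, regions = regions,
        file_attributes = stats::setNames(list(), character())
      )
    }
    txt <- as.character(jsonlite::toJSON(entries, auto_unbox = TRUE,
                                         digits = NA))
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    cp_abort(sprintf("%s is missing required column(s): %s", what,
                     paste(missing, collapse = ", ")), "schema")
  }
  invisible(df)
}

#' Read / write landmark correspondence CSVs
#'
#' On-disk columns are `label, x_px, y_px, visible`; in memory the package
#' uses `label, x, y, visible`.
#'
#' @param path CSV file path.
#' @param corr In-memory correspondence tibble.
#' @return `read_correspondences` returns the tibble; `write_correspondences`
#'   the path, invisibly.
#' @export
read_correspondences <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("label", "x_px", "y_px", "visible"),
                "Correspondence file")
  tibble(label = as.character(df$label), x = as.numeric(df$x_px),
         y = as.numeric(df$y_px), visible = as.logical(df$visible))
}

#' @rdname read_correspondences
#' @export
write_correspondences <- function(corr, path) {
  corr <- validate_correspondences(corr)
  readr::write_csv(
    tibble(label = corr$label, x_px = corr$x, y_px = corr$y,
           visible = corr$visible),
    path
  )
  invisible(path)
}

#' Read / write pose-record CSVs
#'
#' Pose records carry one pose annotation per image: columns `image_id`,
#' `yaw_deg`, `pitch_deg`, `roll_deg` (degrees). On read, angles are
#' re-canonicalized (yaw/roll into `[-180, 180)`, pitch into `[-90, 90]`)
#' with a warning naming how many rows wrapped.
#'
#' @param path CSV file path.
#' @param records Tibble with the pose-record columns.
#' @return `read_pose_records` returns the canonicalized tibble.
#' @export
read_pose_records <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("image_id", "yaw_deg", "pitch_deg", "roll_deg"),
                "Pose record file")
  canon <- canonicalize_pose(df)
  if (any(attr(canon, "wrapped"))) {
    warn(sprintf("%d pose record(s) were outside canonical ranges and were wrapped.",
                 sum(attr(canon, "wrapped"))))
  }
  tibble(image_id = as.character(df$image_id),
         yaw_deg = canon$yaw_deg, pitch_deg = canon$pitch_deg,
         roll_deg = canon$roll_deg)
}

#' @rdname read_pose_records
#' @export
write_pose_records <- function(records, path) {
  check_columns(records, c("image_id", "yaw_deg", "pitch_deg", "roll_deg"),
                "Pose record table")
  readr::write_csv(records[, c("image_id", "yaw_deg", "pitch_deg", "roll_deg")],
                   path)
  invisible(path)
}

#' Read / write dataset manifests
#'
#' The manifest is the dataset index: `sample_id`, `split` (train/val/test),
#' the pose annotation in degrees, and optional file-path columns added by
#' [write_dataset()].
#'
#' @param path CSV file path.
#' @param manifest Manifest tibble.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("sample_id", "split", "yaw_deg", "pitch_deg", "roll_deg"),
                "Manifest")
  if (!all(df$split %in% c("train", "val", "test"))) {
    cp_abort("Manifest `split` values must be train, val or test.", "schema")
  }
  as_tibble(df)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  check_columns(manifest,
                c("sample_id", "split", "yaw_deg", "pitch_deg", "roll_deg"),
                "Manifest")
  readr::write_csv(manifest, path)
  invisible(path)
}
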