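#' Anatomical landmark vocabulary
#'
#' The nine named landmarks a full femoral measurement requires:
#' \describe{
#'   \item{FHC}{femoral head center (center of the fitted head sphere)}
#'   \item{FNC}{femoral neck center}
#'   \item{FNBC}{femoral neck base center (metaphyseal midpoint at the level
#'     of the lesser trochanter)}
#'   \item{LCC, MCC}{lateral / medial condyle centers at the most caudal
#'     aspect of the subchondral surface; together they define the
#'     retrocondylar axis}
#'   \item{PS1, PS2}{proximal diaphyseal (shaft) center points, PS1 the more
#'     proximal}
#'   \item{DS1, DS2}{distal diaphyseal center points, DS1 the more distal}
#' }
#' @export
LANDMARK_NAMES <- c("FHC", "FNC", "FNBC", "LCC", "MCC",
                    "PS1", "PS2", "DS1", "DS2")

landmark_cols <- c("specimen_id", "side", "landmark", "x_mm", "y_mm", "z_mm")

new_landmark_tbl <- function(specimen_id, side, coords,
                             observer = NA_character_,
                             session = NA_integer_) {
  tibble::tibble(
    specimen_id = specimen_id,
    side = side,
    observer = observer,
    session = session,
    landmark = rownames(coords),
    x_mm = unname(coords[, 1]),
    y_mm = unname(coords[, 2]),
    z_mm = unname(coords[, 3])
  )
}

# Validate a single-femur landmark table and return the 9x3 coordinate
# matrix (rownames = landmark names) plus side.
lm_points <- function(landmarks, require = LANDMARK_NAMES) {
  if (!is.data.frame(landmarks)) {
    stop("`landmarks` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(c("side", "landmark", "x_mm", "y_mm", "z_mm"),
                          names(landmarks))
  if (length(missing_cols)) {
    stop("landmark table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(landmarks) == 0) stop("empty landmark table", call. = FALSE)
  side <- unique(landmarks$side)
  if (length(side) != 1L || !side %in% c("left", "right")) {
    stop("landmark table must describe a single femur with side ",
         "'left' or 'right'", call. = FALSE)
  }
  if (anyDuplicated(landmarks$landmark)) {
    stop("duplicated landmark names in a single-femur table", call. = FALSE)
  }
  absent <- setdiff(require, landmarks$landmark)
  if (length(absent)) {
    stop("missing landmark(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(landmarks[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(xyz))) stop("non-finite landmark coordinates",
                                 call. = FALSE)
  dimnames(xyz) <- list(landmarks$landmark, NULL)
  list(xyz = xyz, side = side,
       specimen_id = if ("specimen_id" %in% names(landmarks))
         unique(landmarks$specimen_id)[1] else NA_character_,
       observer = if ("observer" %in% names(landmarks))
         unique(landmarks$observer)[1] else NA_character_,
       session = if ("session" %in% names(landmarks))
         unique(landmarks$session)[1] else NA_integer_)
}

set_coords <- function(landmarks, xyz) {
  idx <- match(landmarks$landmark, rownames(xyz))
  landmarks$x_mm <- unname(xyz[idx, 1])
  landmarks$y_mm <- unname(xyz[idx, 2])
  landmarks$z_mm <- unname(xyz[idx, 3])
  landmarks
}

#' Read / write landmark coordinate tables
#'
#' Landmark CSVs have one row per named landmark per specimen, side,
#' observer and session, with coordinates in millimetres: columns
#' `specimen_id, side, observer, session, landmark, x_mm, y_mm, z_mm`
#' (observer/session optional on read).
#'
#' @param path File path.
#' @param landmarks A landmark tibble as produced by
#'   [build_canonical_landmarks()] or [simulate_cohort()].
#' @return `read_landmarks()` returns a tibble; `write_landmarks()` returns
#'   `landmarks` invisibly.
#' @export
read_landmarks <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("specimen_id", "side", "landmark", "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols)) {
    stop("landmark CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(out$landmark), LANDMARK_NAMES)
  if (length(bad)) {
    stop("unknown landmark name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  readr::write_csv(landmarks, path)
  invisible(landmarks)
}

#' Write a point cloud as plain XYZ text
#'
#' One `x y z` triple per line, space separated, for interoperability with
#' point-cloud viewers.
#'
#' @param points Data frame with columns `x`, `y`, `z` (mm).
#' @param path Output file path.
#' @return `points`, invisibly.
#' @export
write_xyz <- function(points, path) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  utils::write.table(points[, c("x", "y", "z")], path,
                     row.names = FALSE, col.names = FALSE)
  invisible(points)
}
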