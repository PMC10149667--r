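#' Least-squares sphere fit
#'
#' Fits a sphere to a 3D point cloud: first the algebraic linear least
#' squares solution (minimizing the residuals of `|p - c|^2 - r^2` via the
#' linearized system), then, by default, geometric Gauss-Newton refinement of
#' the center minimizing the sum of squared orthogonal distances
#' `(|p - c| - r)^2`, with the radius profiled out as the mean distance.
#' The femoral head center is the center of this fit over points picked on
#' the head's bearing surface.
#'
#' @param points Data frame of points; columns `x`, `y`, `z` or
#'   `x_mm`, `y_mm`, `z_mm` (mm).
#' @param refine Run the geometric refinement (default `TRUE`).
#' @return An object of class `sphere_fit` with fields `center` (length-3),
#'   `radius`, `rms_residual` (RMS orthogonal distance to the sphere) and
#'   `n_points`. `tidy()` returns it as a one-row tibble.
#' @export
#' @examples
#' pts <- sample_head_surface(phantom_spec(), 300, noise_sigma_mm = 0.1,
#'                            seed = 7)
#' fit_sphere(pts)
fit_sphere <- function(points, refine = TRUE) {
  P <- points_matrix(points)
  n <- nrow(P)
  if (n < 4) {
    stop("degenerate configuration: at least 4 points are required",
         call. = FALSE)
  }
  # |p|^2 = 2 c.p + (r^2 - |c|^2): linear in (c, k)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qr_ <- qr(A)
  if (qr_$rank < 4) {
    stop("degenerate configuration: points do not determine a sphere ",
         "(coplanar or collinear)", call. = FALSE)
  }
  beta <- qr.coef(qr_, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate configuration: non-positive fitted radius",
         call. = FALSE)
  }

  if (refine) {
    # Gauss-Newton on c with r profiled out: residuals d_i - mean(d)
    for (iter in seq_len(50)) {
      diffs <- sweep(P, 2, center)
      d <- sqrt(rowSums(diffs^2))
      if (any(d < 1e-12)) break
      r <- mean(d)
      res <- d - r
      J <- -diffs / d                      # d(d_i)/dc
      J <- sweep(J, 2, colMeans(J))        # profile out r
      step <- tryCatch(qr.solve(crossprod(J), crossprod(J, res)),
                       error = function(e) NULL)
      if (is.null(step)) break
      center <- center - as.numeric(step)
      if (vnorm(as.numeric(step)) < 1e-12) break
    }
  }
  d <- sqrt(rowSums(sweep(P, 2, center)^2))
  radius <- mean(d)
  structure(list(center = unname(center), radius = radius,
                 rms_residual = sqrt(mean((d - radius)^2)),
                 n_points = n),
            class = "sphere_fit")
}

points_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    return(unname(points))
  }
  cols <- if (all(c("x", "y", "z") %in% names(points))) {
    c("x", "y", "z")
  } else if (all(c("x_mm", "y_mm", "z_mm") %in% names(points))) {
    c("x_mm", "y_mm", "z_mm")
  } else {
    stop("`points` needs columns x/y/z or x_mm/y_mm/z_mm", call. = FALSE)
  }
  P <- as.matrix(points[, cols])
  if (!all(is.finite(P))) stop("non-finite point coordinates", call. = FALSE)
  unname(P)
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "Sphere fit: center (%.3f, %.3f, %.3f) mm, radius %.3f mm\n  RMS residual %.4f mm over %d points\n",
    x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual,
    x$n_points))
  invisible(x)
}

#' Femoral longitudinal axis from diaphyseal center points
#'
#' Three variants: `pd` uses the two proximal shaft centers, `dd` the two
#' distal ones, `td` an orthogonal least-squares (total) line through all
#' four. Every variant is returned pointing proximally (toward the proximal
#' shaft centers), regardless of landmark input order.
#'
#' @param landmarks Landmark tibble for one femur.
#' @param variant `"pd"`, `"dd"` or `"td"`.
#' @return A list with `direction` (proximally pointing unit vector) and
#'   `origin` (a point on the axis).
#' @export
longitudinal_axis <- function(landmarks, variant = c("td", "pd", "dd")) {
  variant <- match.arg(variant)
  need <- switch(variant, pd = c("PS1", "PS2"), dd = c("DS1", "DS2"),
                 td = c("PS1", "PS2", "DS1", "DS2"))
  p <- lm_points(landmarks, require = c("PS1", "PS2", "DS1", "DS2"))
  xyz <- p$xyz
  proximal_ref <- colMeans(xyz[c("PS1", "PS2"), ]) -
    colMeans(xyz[c("DS1", "DS2"), ])
  pts <- xyz[need, , drop = FALSE]
  if (variant == "td") {
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    dir <- sv$v[, 1]
    origin <- ctr
  } else {
    dir <- pts[1, ] - pts[2, ]
    if (vnorm(dir) < 1e-9) {
      stop("degenerate axis: coincident shaft landmarks for variant '",
           variant, "'", call. = FALSE)
    }
    origin <- colMeans(pts)
  }
  dir <- unitize(dir, "longitudinal axis")
  if (sum(dir * proximal_ref) < 0) dir <- -dir
  list(direction = dir, origin = unname(origin))
}

#' Construct the bone-centered coordinate system
#'
#' Builds the orthonormal frame the projected angles are measured in:
#' \itemize{
#'   \item `L`: longitudinal unit axis (variant `td` by default), pointing
#'     proximally; its normal plane is the transverse plane.
#'   \item `M`: the retrocondylar axis (LCC to MCC, lateral to medial)
#'     orthogonalized against `L`; with `L` it spans the dorsal plane.
#'   \item `C`: craniocaudal unit axis, pointing cranially, obtained as
#'     `s * (L x M)` with side sign `s` (+1 left, -1 right) so the frame is
#'     cranial-positive for both sides.
#' }
#' The origin is the midpoint of the condyle centers. The frame is
#' right-handed for left femora and left-handed for right femora; this is
#' what keeps signed torsion (antetorsion positive) side-symmetric.
#'
#' @param landmarks Landmark tibble for one femur.
#' @param axis_variant Longitudinal axis variant, see [longitudinal_axis()].
#' @return An object of class `bone_frame` with unit vectors `L`, `M`, `C`,
#'   the `origin`, `side` and `axis_variant`.
#' @export
build_bone_frame <- function(landmarks, axis_variant = c("td", "pd", "dd")) {
  axis_variant <- match.arg(axis_variant)
  p <- lm_points(landmarks, require = c("LCC", "MCC", "PS1", "PS2",
                                        "DS1", "DS2"))
  Lax <- longitudinal_axis(landmarks, axis_variant)
  Lhat <- Lax$direction
  condyle <- p$xyz["MCC", ] - p$xyz["LCC", ]
  if (vnorm(condyle) < 1e-9) {
    stop("degenerate frame: condyle centers coincide", call. = FALSE)
  }
  Mraw <- condyle - sum(condyle * Lhat) * Lhat
  if (vnorm(Mraw) < 1e-9 * vnorm(condyle)) {
    stop("degenerate frame: retrocondylar axis is parallel to the ",
         "longitudinal axis", call. = FALSE)
  }
  Mhat <- unitize(Mraw)
  s <- if (p$side == "left") 1 else -1
  Chat <- s * cross3(Lhat, Mhat)
  structure(list(origin = unname((p$xyz["LCC", ] + p$xyz["MCC", ]) / 2),
                 L = unname(Lhat), M = unname(Mhat), C = unname(Chat),
                 side = p$side, side_sign = s, axis_variant = axis_variant),
            class = "bone_frame")
}

#' @export
print.bone_frame <- function(x, ...) {
  cat(sprintf("Bone-centered frame (%s femur, %s axis)\n", x$side,
              x$axis_variant))
  mat <- rbind(origin = x$origin, L = x$L, M = x$M, C = x$C)
  print(round(mat, 6))
  invisible(x)
}

#' @rdname build_bone_frame
#' @param x A `bone_frame`.
#' @param ... Unused.
#' @export
tidy.bone_frame <- function(x, ...) {
  tibble::tibble(
    component = c("origin", "L", "M", "C"),
    x = c(x$origin[1], x$L[1], x$M[1], x$C[1]),
    y = c(x$origin[2], x$L[2], x$M[2], x$C[2]),
    z = c(x$origin[3], x$L[3], x$M[3], x$C[3])
  )
}

#' @rdname fit_sphere
#' @param x A `sphere_fit`.
#' @param ... Unused.
#' @export
tidy.sphere_fit <- function(x, ...) {
  tibble::tibble(center_x = x$center[1], center_y = x$center[2],
                 center_z = x$center[3], radius = x$radius,
                 rms_residual = x$rms_residual, n_points = x$n_points)
}
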