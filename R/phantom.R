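#' Build ground-truth landmarks for the parametric femur phantom
#'
#' Constructs the nine anatomical landmarks in the canonical bone frame:
#' the long axis along +z (proximal), the cranial direction along +y, and the
#' medial direction along +x for left femora (-x for right, i.e. the right
#' femur is the mirror image of the left through the sagittal plane).
#' Diaphyseal center points lie exactly on the long axis, the condyle centers
#' sit symmetric about it with the stated caudal offset, FNBC sits on the
#' axis at the proximal metaphyseal level, and FHC is placed so that the
#' FNBC-to-FHC axis makes exactly `nominal_inclination_deg` with the distally
#' pointing long axis and exactly `nominal_antetorsion_deg` of projected
#' antetorsion relative to the retrocondylar axis. A nonzero
#' `hinge_angle_deg` is applied via [apply_hinge()]; a nonzero
#' `shaft_bend_deg` tilts the proximal segment medially within the dorsal
#' plane.
#'
#' @param spec A [phantom_spec()].
#' @return A landmark tibble (one row per landmark).
#' @export
build_canonical_landmarks <- function(spec) {
  spec <- validate_phantom_spec(spec)
  L <- spec$shaft_length
  m <- if (spec$side == "left") 1 else -1   # medial direction sign on x
  Mhat <- c(m, 0, 0); Chat <- c(0, 1, 0); Lhat <- c(0, 0, 1)

  tau <- spec$nominal_antetorsion_deg * DEG
  incl <- spec$nominal_inclination_deg * DEG
  neck_dir <- sin(incl) * (cos(tau) * Mhat + sin(tau) * Chat) -
    cos(incl) * Lhat

  fnbc <- c(0, 0, L)
  fhc <- fnbc + spec$neck_length * neck_dir
  fnc <- fnbc + 0.5 * spec$neck_length * neck_dir +
    spec$fnc_offset_cranial_mm * Chat +
    spec$fnc_offset_proximal_mm * Lhat

  w <- spec$condyle_half_width
  cc <- spec$condyle_caudal_offset
  xyz <- rbind(
    FHC = fhc,
    FNC = fnc,
    FNBC = fnbc,
    LCC = c(-m * w, -cc, 0),
    MCC = c(m * w, -cc, 0),
    PS1 = c(0, 0, spec$ps_level_fractions[2] * L),
    PS2 = c(0, 0, spec$ps_level_fractions[1] * L),
    DS1 = c(0, 0, spec$ds_level_fractions[1] * L),
    DS2 = c(0, 0, spec$ds_level_fractions[2] * L)
  )

  out <- new_landmark_tbl(spec$specimen_id, spec$side, xyz)

  if (spec$shaft_bend_deg != 0) {
    z_bend <- spec$hinge_level_fraction * L
    Rb <- rotation_about_axis(Chat, m * spec$shaft_bend_deg)
    out <- rotate_proximal(out, Rb, z_bend)
  }
  if (spec$hinge_angle_deg != 0) {
    out <- apply_hinge(out, spec$hinge_angle_deg, spec$hinge_level_fraction)
  }
  out
}

# Rotate landmarks strictly proximal to canonical level z_level about an axis
# through (0, 0, z_level).
rotate_proximal <- function(landmarks, R, z_level) {
  p <- lm_points(landmarks)
  xyz <- p$xyz
  prox <- xyz[, 3] > z_level + 1e-9
  centred <- sweep(xyz[prox, , drop = FALSE], 2, c(0, 0, z_level))
  xyz[prox, ] <- centred %*% t(R) +
    matrix(c(0, 0, z_level), sum(prox), 3, byrow = TRUE)
  set_coords(landmarks, xyz)
}

#' Twist the phantom's diaphyseal hinge
#'
#' Rotates every landmark proximal to the hinge level about the canonical
#' long axis, leaving distal landmarks untouched; the resulting true torsion
#' is the baseline antetorsion plus `hinge_angle_deg` exactly. Positive hinge
#' angles increase antetorsion for either side (for right femora the spatial
#' rotation is mirrored accordingly). Landmarks must be in the canonical
#' frame (long axis = z through the origin).
#'
#' @param landmarks Canonical-frame landmark tibble.
#' @param hinge_angle_deg Hinge rotation, degrees.
#' @param level_fraction Hinge level as a fraction of the FNBC height
#'   (default 0.5, the mid-diaphyseal cut).
#' @return The hinged landmark tibble.
#' @export
apply_hinge <- function(landmarks, hinge_angle_deg, level_fraction = 0.5) {
  p <- lm_points(landmarks, require = "FNBC")
  s <- if (p$side == "left") 1 else -1
  z_h <- level_fraction * p$xyz["FNBC", 3]
  R <- rotation_about_axis(c(0, 0, 1), s * hinge_angle_deg)
  rotate_proximal(landmarks, R, z_h)
}

#' Apply a rigid pose to a landmark set
#'
#' Rigidly transforms every landmark (`x -> R x + t`). All downstream angles
#' are pose-invariant, emulating arbitrary positioning of the bone in the
#' scanner gantry.
#'
#' @param landmarks Landmark tibble.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Numeric length-3 translation, mm.
#' @return The transformed landmark tibble.
#' @export
apply_pose <- function(landmarks, rotation = diag(3),
                       translation = c(0, 0, 0)) {
  if (!is_proper_rotation(rotation)) {
    stop("invalid transform: `rotation` must be orthonormal with ",
         "determinant +1", call. = FALSE)
  }
  p <- lm_points(landmarks, require = character())
  xyz <- p$xyz %*% t(rotation) +
    matrix(translation, nrow(p$xyz), 3, byrow = TRUE)
  set_coords(landmarks, xyz)
}

#' Sample noisy points on the femoral head bearing surface
#'
#' Draws points uniformly on the spherical cap of the phantom's head (radius
#' `head_radius`, centered at the true FHC, cap oriented along the neck
#' axis), then adds isotropic Gaussian noise; this is the input the head
#' sphere fit consumes.
#'
#' @param spec A [phantom_spec()] (canonical, unhinged geometry).
#' @param n_points Number of points (>= 4).
#' @param cap_halfangle_deg Cap half-angle in (0, 90].
#' @param noise_sigma_mm Isotropic Gaussian noise SD, mm.
#' @param seed Optional integer seed.
#' @return Tibble with columns `x`, `y`, `z` (mm).
#' @export
#' @examples
#' pts <- sample_head_surface(phantom_spec(), 200, seed = 1)
#' fit_sphere(pts)
sample_head_surface <- function(spec, n_points, cap_halfangle_deg = 60,
                                noise_sigma_mm = 0, seed = NULL) {
  spec <- validate_phantom_spec(spec)
  if (n_points < 4) {
    stop("too few points: a sphere needs at least 4", call. = FALSE)
  }
  if (cap_halfangle_deg <= 0 || cap_halfangle_deg > 90) {
    stop("`cap_halfangle_deg` must lie in (0, 90]", call. = FALSE)
  }
  lm <- build_canonical_landmarks(spec)
  p <- lm_points(lm, require = c("FHC", "FNBC"))
  axis <- unitize(p$xyz["FHC", ] - p$xyz["FNBC", ], "neck axis")
  # orthonormal basis around the cap axis
  seed_vec <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3(axis, seed_vec))
  e2 <- cross3(axis, e1)
  with_local_seed(seed, {
    cos_th <- stats::runif(n_points, cos(cap_halfangle_deg * DEG), 1)
    sin_th <- sqrt(pmax(0, 1 - cos_th^2))
    phi <- stats::runif(n_points, 0, 2 * pi)
    dirs <- outer(cos_th, axis) +
      outer(sin_th * cos(phi), e1) + outer(sin_th * sin(phi), e2)
    pts <- matrix(p$xyz["FHC", ], n_points, 3, byrow = TRUE) +
      spec$head_radius * dirs
    if (noise_sigma_mm > 0) {
      pts <- pts + matrix(stats::rnorm(3 * n_points, sd = noise_sigma_mm),
                          n_points, 3)
    }
    tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
}

#' Perturb landmarks with observer placement noise
#'
#' Displaces each landmark by independent isotropic Gaussian noise,
#' emulating intra-/inter-observer variability of manual landmark placement.
#'
#' @param landmarks Landmark tibble.
#' @param sigma_mm Noise SD per coordinate, mm (>= 0).
#' @param seed Optional integer seed (same seed, same output).
#' @return The perturbed landmark tibble.
#' @export
perturb_observer <- function(landmarks, sigma_mm, seed = NULL) {
  if (sigma_mm < 0) stop("`sigma_mm` must be >= 0", call. = FALSE)
  if (sigma_mm == 0) return(landmarks)
  n <- nrow(landmarks)
  with_local_seed(seed, {
    noise <- matrix(stats::rnorm(3 * n, sd = sigma_mm), n, 3)
    landmarks$x_mm <- landmarks$x_mm + noise[, 1]
    landmarks$y_mm <- landmarks$y_mm + noise[, 2]
    landmarks$z_mm <- landmarks$z_mm + noise[, 3]
    landmarks
  })
}

#' Simulate a goniometer reading
#'
#' Reading = round-to-increment(true angle + alignment bias + Gaussian
#' reading noise), with ties rounded half-away-from-zero (a symmetric
#' physical scale is read outward from zero, so e.g. -68.5 reads -69 at a
#' 1-degree increment).
#'
#' @param true_angle_deg True angle(s), degrees (vectorized).
#' @param model A [goniometer_model()].
#' @param seed Optional seed overriding `model$seed`.
#' @return Numeric vector of readings, degrees.
#' @export
simulate_goniometer <- function(true_angle_deg, model = goniometer_model(),
                                seed = NULL) {
  stopifnot(inherits(model, "goniometer_model"))
  seed <- if (is.null(seed)) model$seed else seed
  with_local_seed(seed, {
    noisy <- true_angle_deg + model$alignment_bias_deg +
      if (model$reading_sigma_deg > 0) {
        stats::rnorm(length(true_angle_deg), sd = model$reading_sigma_deg)
      } else 0
    round_half_away(noisy, model$reading_increment_deg)
  })
}
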