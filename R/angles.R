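#' Project a vector into a plane
#'
#' Removes the component of `v` along the plane's unit `normal`:
#' `v - (v . normal) normal`.
#'
#' @param v Numeric length-3 vector.
#' @param normal Unit normal of the plane.
#' @return The projected vector (possibly near zero when `v` is parallel to
#'   `normal`; callers must check before normalizing).
#' @export
project_to_plane <- function(v, normal) {
  stopifnot(length(v) == 3, length(normal) == 3)
  if (abs(vnorm(normal) - 1) > 1e-8) {
    stop("`normal` must be a unit vector", call. = FALSE)
  }
  v - sum(v * normal) * normal
}

#' Signed angle between two vectors projected into a plane
#'
#' Projects `u` and `v` into the plane with unit `normal` and returns the
#' angle from the projection of `u` to the projection of `v`, in
#' (-180, 180], with the sign given by the right-hand rule about `normal`.
#'
#' @param u,v Numeric length-3 vectors.
#' @param normal Unit plane normal.
#' @return Signed angle in degrees.
#' @export
#' @examples
#' signed_angle_in_plane(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))  # +90
signed_angle_in_plane <- function(u, v, normal) {
  pu <- project_to_plane(u, normal)
  pv <- project_to_plane(v, normal)
  if (vnorm(pu) < 1e-9 * max(vnorm(u), 1) ||
      vnorm(pv) < 1e-9 * max(vnorm(v), 1)) {
    stop("degenerate projection: vector is (near-)parallel to the plane ",
         "normal", call. = FALSE)
  }
  ang <- atan2(sum(cross3(pu, pv) * normal), sum(pu * pv)) / DEG
  if (ang <= -180) ang + 360 else ang
}

# Unprojected angle between two 3D vectors, degrees in [0, 180].
angle_between <- function(u, v) {
  uu <- unitize(u, "axis"); vv <- unitize(v, "axis")
  acos(max(-1, min(1, sum(uu * vv)))) / DEG
}

neck_axis <- function(xyz, neck_variant) {
  base <- switch(neck_variant, NC = "FNC", NBC = "FNBC")
  v <- xyz["FHC", ] - xyz[base, ]
  if (vnorm(v) < 1e-9) {
    stop("degenerate axis: FHC coincides with ", base, call. = FALSE)
  }
  v
}

#' Femoral torsion angle (FTA)
#'
#' Signed angle between the retrocondylar axis and the femoral neck axis,
#' both projected into the transverse plane (normal to the longitudinal
#' axis). Antetorsion (cranial deviation of the neck) is positive and
#' retrotorsion negative for either side. The neck axis runs from FNC
#' (variant `"NC"`) or FNBC (variant `"NBC"`) to the femoral head center.
#'
#' @param landmarks Landmark tibble for one femur.
#' @param neck_variant `"NBC"` or `"NC"`.
#' @param axis_variant Longitudinal axis defining the transverse plane
#'   (default `"td"`).
#' @return Signed torsion in degrees, in (-180, 180].
#' @export
#' @examples
#' lm <- build_canonical_landmarks(phantom_spec())
#' femoral_torsion(lm, "NBC")  # 21.5
femoral_torsion <- function(landmarks, neck_variant = c("NBC", "NC"),
                            axis_variant = c("td", "pd")) {
  neck_variant <- match.arg(neck_variant)
  axis_variant <- match.arg(axis_variant)
  frame <- build_bone_frame(landmarks, axis_variant)
  p <- lm_points(landmarks)
  torsion_from_frame(p$xyz, frame, neck_variant)
}

torsion_from_frame <- function(xyz, frame, neck_variant) {
  condyle <- xyz["MCC", ] - xyz["LCC", ]
  neck <- neck_axis(xyz, neck_variant)
  # normal s*L makes the rotation from M toward cranial positive on both
  # sides (C = s * L x M)
  signed_angle_in_plane(condyle, neck, frame$side_sign * frame$L)
}

#' Femoral neck inclination angle (FIA)
#'
#' Direct (unprojected) 3D angle between the neck axis (neck base to femoral
#' head center) and the distally pointing longitudinal axis; near 135 degrees
#' in normal femora.
#'
#' @inheritParams femoral_torsion
#' @param axis_variant Longitudinal axis variant (default `"td"`).
#' @return Angle in degrees, in (0, 180).
#' @export
femoral_inclination <- function(landmarks, neck_variant = c("NBC", "NC"),
                                axis_variant = c("td", "pd", "dd")) {
  neck_variant <- match.arg(neck_variant)
  axis_variant <- match.arg(axis_variant)
  p <- lm_points(landmarks)
  Lax <- longitudinal_axis(landmarks, axis_variant)
  angle_between(neck_axis(p$xyz, neck_variant), -Lax$direction)
}

#' Femoral varus angle (FVA)
#'
#' Projects the proximally pointing reference longitudinal axis (`pd` or
#' `td`) and the distally pointing distal (`dd`) axis into the dorsal plane
#' (normal = craniocaudal axis) and returns the unsigned angle between them:
#' 180 degrees for a perfectly straight bone, below 180 when the shaft
#' deviates within the dorsal plane. The signed deviation (180 - angle,
#' positive when the distal segment deviates medially, i.e. varus) is
#' available from [measure_all()] as `fva_*_dev`.
#'
#' @param landmarks Landmark tibble for one femur.
#' @param reference_variant `"pd"` or `"td"` reference axis.
#' @param frame_axis Axis variant used to build the dorsal-plane frame
#'   (default `"td"`).
#' @return Unsigned projected angle in degrees (near 180).
#' @export
femoral_varus <- function(landmarks, reference_variant = c("pd", "td"),
                          frame_axis = "td") {
  reference_variant <- match.arg(reference_variant)
  frame <- build_bone_frame(landmarks, frame_axis)
  varus_from_frame(landmarks, frame, reference_variant)$angle
}

varus_from_frame <- function(landmarks, frame, reference_variant) {
  ref <- longitudinal_axis(landmarks, reference_variant)$direction
  dd_distal <- -longitudinal_axis(landmarks, "dd")$direction
  pr <- project_to_plane(ref, frame$C)
  pdd <- project_to_plane(dd_distal, frame$C)
  if (vnorm(pr) < 1e-9 || vnorm(pdd) < 1e-9) {
    stop("degenerate projection: shaft axis parallel to the craniocaudal ",
         "axis", call. = FALSE)
  }
  ang <- angle_between(pr, pdd)
  medial <- sum((unitize(pr) + unitize(pdd)) * frame$M)
  dev <- (180 - ang) * if (abs(medial) < 1e-12) 0 else sign(medial)
  list(angle = ang, deviation = dev)
}

#' Measure all six femoral angle variants
#'
#' Computes FTA-NC/NBC (projected torsion), FIA-NC/NBC (direct neck
#' inclination) and FVA-pd/td (projected varus) from one femur's landmarks
#' with a single shared frame construction, and records the axis choices so
#' results stay technique-labeled.
#'
#' @param landmarks Landmark tibble for one femur (one observer/session).
#' @param torsion_axis Longitudinal axis variant defining the transverse
#'   plane (default `"td"`).
#' @param fia_axis Longitudinal axis variant for inclination (default
#'   `"td"`).
#' @return A one-row tibble: identifiers, `fta_nc`, `fta_nbc`, `fia_nc`,
#'   `fia_nbc`, `fva_pd`, `fva_td` (degrees), signed varus deviations
#'   `fva_pd_dev`, `fva_td_dev`, and technique tags.
#' @export
#' @examples
#' measure_all(build_canonical_landmarks(phantom_spec()))
measure_all <- function(landmarks, torsion_axis = "td", fia_axis = "td") {
  p <- lm_points(landmarks)
  frame <- build_bone_frame(landmarks, torsion_axis)
  Lax <- longitudinal_axis(landmarks, fia_axis)
  v_pd <- varus_from_frame(landmarks, frame, "pd")
  v_td <- varus_from_frame(landmarks, frame, "td")
  tibble::tibble(
    specimen_id = p$specimen_id,
    side = p$side,
    observer = p$observer,
    session = p$session,
    fta_nc = torsion_from_frame(p$xyz, frame, "NC"),
    fta_nbc = torsion_from_frame(p$xyz, frame, "NBC"),
    fia_nc = angle_between(neck_axis(p$xyz, "NC"), -Lax$direction),
    fia_nbc = angle_between(neck_axis(p$xyz, "NBC"), -Lax$direction),
    fva_pd = v_pd$angle,
    fva_td = v_td$angle,
    fva_pd_dev = v_pd$deviation,
    fva_td_dev = v_td$deviation,
    torsion_axis = torsion_axis,
    fia_axis = fia_axis
  )
}

#' Measure angles for every femur in a long landmark table
#'
#' Splits a landmark table by specimen, side, observer and session (whichever
#' identifier columns are present) and applies [measure_all()] to each group.
#'
#' @param landmarks Long landmark tibble (several femora / sessions).
#' @inheritParams measure_all
#' @return A tibble with one row per measured femur-session.
#' @export
measure_angles <- function(landmarks, torsion_axis = "td", fia_axis = "td") {
  keys <- intersect(c("specimen_id", "side", "observer", "session"),
                    names(landmarks))
  landmarks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_split() |>
    purrr::map(measure_all, torsion_axis = torsion_axis,
               fia_axis = fia_axis) |>
    purrr::list_rbind()
}
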