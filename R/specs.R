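#' Parametric femur phantom specification
#'
#' Describes an idealized canine femur phantom: a straight diaphysis with a
#' mid-diaphyseal rotation hinge, a retrocondylar condyle pair, and a neck /
#' head assembly set at a nominal inclination and antetorsion. The default
#' antetorsion of 21.5 degrees is the physiological baseline that corresponds
#' to the hinge's 0 degree setting; twisting the hinge by h degrees yields a
#' true torsion of 21.5 + h.
#'
#' Geometry defaults (shaft length, condyle half-width, caudal offset, neck
#' length, head radius) are generic plumbing values of realistic magnitude
#' for a medium dog; no downstream statistic depends on them.
#'
#' @param shaft_length Diaphysis length, mm.
#' @param condyle_half_width Half the intercondylar distance, mm.
#' @param condyle_caudal_offset Caudal offset of the condyle centers from the
#'   diaphyseal axis, mm.
#' @param neck_length FNBC-to-FHC distance, mm.
#' @param head_radius Femoral head sphere radius, mm.
#' @param nominal_inclination_deg 3D angle between the neck axis and the
#'   distally pointing long axis, degrees; must lie in (90, 180).
#' @param nominal_antetorsion_deg Baseline projected antetorsion, degrees.
#' @param hinge_level_fraction Fraction of shaft length (strictly inside
#'   (0, 1)) at which the transverse hinge cut sits; 0.5 = mid-diaphyseal.
#' @param hinge_angle_deg Preset rotation of the hinge, degrees; positive
#'   increases antetorsion.
#' @param side `"left"` or `"right"`.
#' @param fnc_offset_cranial_mm,fnc_offset_proximal_mm Displacement of the
#'   FNC landmark off the geometric neck axis, cranially and proximally (mm).
#'   Zero in the ideal phantom; nonzero values emulate the anatomical neck
#'   center, which does not sit on the FNBC-FHC chord.
#' @param shaft_bend_deg Varus bend of the proximal segment within the dorsal
#'   plane at the hinge level, degrees (medial deviation positive); 0 = the
#'   straight phantom.
#' @param ps_level_fractions,ds_level_fractions Fractions of shaft length at
#'   which the two proximal (PS2, PS1) and two distal (DS1, DS2) diaphyseal
#'   center points are taken.
#' @param specimen_id Identifier carried into output tables.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(hinge_angle_deg = -30)
#' lm <- build_canonical_landmarks(spec)
#' femoral_torsion(lm, "NBC")  # 21.5 - 30 = -8.5
phantom_spec <- function(shaft_length = 150,
                         condyle_half_width = 10,
                         condyle_caudal_offset = 5,
                         neck_length = 25,
                         head_radius = 9,
                         nominal_inclination_deg = 135,
                         nominal_antetorsion_deg = 21.5,
                         hinge_level_fraction = 0.5,
                         hinge_angle_deg = 0,
                         side = c("left", "right"),
                         fnc_offset_cranial_mm = 0,
                         fnc_offset_proximal_mm = 0,
                         shaft_bend_deg = 0,
                         ps_level_fractions = c(0.65, 0.85),
                         ds_level_fractions = c(0.15, 0.30),
                         specimen_id = "phantom") {
  side <- match.arg(side)
  spec <- list(
    shaft_length = shaft_length,
    condyle_half_width = condyle_half_width,
    condyle_caudal_offset = condyle_caudal_offset,
    neck_length = neck_length,
    head_radius = head_radius,
    nominal_inclination_deg = nominal_inclination_deg,
    nominal_antetorsion_deg = nominal_antetorsion_deg,
    hinge_level_fraction = hinge_level_fraction,
    hinge_angle_deg = hinge_angle_deg,
    side = side,
    fnc_offset_cranial_mm = fnc_offset_cranial_mm,
    fnc_offset_proximal_mm = fnc_offset_proximal_mm,
    shaft_bend_deg = shaft_bend_deg,
    ps_level_fractions = sort(ps_level_fractions),
    ds_level_fractions = sort(ds_level_fractions),
    specimen_id = specimen_id
  )
  validate_phantom_spec(structure(spec, class = "phantom_spec"))
}

validate_phantom_spec <- function(spec) {
  lens <- c("shaft_length", "condyle_half_width", "condyle_caudal_offset",
            "neck_length", "head_radius")
  for (f in lens) {
    if (!is.numeric(spec[[f]]) || length(spec[[f]]) != 1 ||
        !is.finite(spec[[f]]) || spec[[f]] <= 0) {
      stop("invalid phantom spec: `", f, "` must be a positive length (mm)",
           call. = FALSE)
    }
  }
  if (spec$hinge_level_fraction <= 0 || spec$hinge_level_fraction >= 1) {
    stop("invalid phantom spec: `hinge_level_fraction` must lie strictly ",
         "inside (0, 1)", call. = FALSE)
  }
  if (spec$nominal_inclination_deg <= 90 ||
      spec$nominal_inclination_deg >= 180) {
    stop("invalid phantom spec: `nominal_inclination_deg` must lie in ",
         "(90, 180)", call. = FALSE)
  }
  if (length(spec$ps_level_fractions) != 2 ||
      length(spec$ds_level_fractions) != 2 ||
      any(c(spec$ps_level_fractions, spec$ds_level_fractions) <= 0) ||
      any(c(spec$ps_level_fractions, spec$ds_level_fractions) >= 1)) {
    stop("invalid phantom spec: shaft level fractions must be two values in ",
         "(0, 1)", call. = FALSE)
  }
  spec
}

#' Goniometer reading model
#'
#' A transparent plastic goniometer read at a fixed increment: the reading is
#' the true angle plus an alignment bias plus Gaussian reading noise, rounded
#' half-away-from-zero to the increment.
#'
#' @param reading_increment_deg Scale increment, degrees (default 1).
#' @param alignment_bias_deg Systematic offset added before rounding,
#'   degrees (e.g. mild rod malalignment in a physical model).
#' @param reading_sigma_deg SD of Gaussian reading noise, degrees.
#' @param seed Optional integer seed used by [simulate_goniometer()].
#' @return An object of class `goniometer_model`.
#' @export
goniometer_model <- function(reading_increment_deg = 1,
                             alignment_bias_deg = 0,
                             reading_sigma_deg = 0,
                             seed = NULL) {
  if (reading_increment_deg <= 0) {
    stop("`reading_increment_deg` must be > 0", call. = FALSE)
  }
  if (reading_sigma_deg < 0) {
    stop("`reading_sigma_deg` must be >= 0", call. = FALSE)
  }
  structure(list(reading_increment_deg = reading_increment_deg,
                 alignment_bias_deg = alignment_bias_deg,
                 reading_sigma_deg = reading_sigma_deg,
                 seed = seed),
            class = "goniometer_model")
}

#' Clinical cohort simulation specification
#'
#' Describes a bilateral cohort measured by several observers: per-dog true
#' angle parameters are drawn from Gaussian distributions, a phantom is built
#' per dog and side, and each (observer, session) re-measures it after
#' landmark-level placement noise. Observer 1 contributes
#' `repeat_sessions_observer1` sessions (intraobserver repeatability);
#' further observers contribute one session each (interobserver
#' reproducibility).
#'
#' Angle distribution defaults follow the magnitudes reported for clinical
#' canine femora (torsion about 23 degrees, neck inclination about 137
#' degrees, a small varus bend so projected varus angles fall near 175
#' degrees), with SD 3 degrees; the FNC offsets reproduce the systematic
#' NC-vs-NBC differences of a real neck center. All are overridable.
#'
#' @param n_dogs Number of dogs (default 34).
#' @param sides Character vector of sides measured per dog.
#' @param torsion_mean,torsion_sd True antetorsion distribution, degrees.
#' @param inclination_mean,inclination_sd True neck inclination distribution,
#'   degrees.
#' @param varus_bend_mean,varus_bend_sd True dorsal-plane shaft bend,
#'   degrees.
#' @param fnc_offset_cranial_mm,fnc_offset_proximal_mm FNC landmark offsets,
#'   see [phantom_spec()].
#' @param observer_sigma_mm Per-observer landmark placement noise SD (mm);
#'   recycled to `n_observers`.
#' @param n_observers Number of observers (default 2).
#' @param repeat_sessions_observer1 Sessions for observer 1 (default 2).
#' @param within_subject_cv_pct Optional explicit within-subject coefficient
#'   of variation (percent) injected as multiplicative Gaussian measurement
#'   noise on every reported angle, independent across sessions. `NULL`
#'   (default) disables it; use it when a known CV must be recoverable.
#' @param seed Top-level integer seed; all sub-streams derive from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_dogs = 34,
                        sides = c("left", "right"),
                        torsion_mean = 23, torsion_sd = 3,
                        inclination_mean = 137, inclination_sd = 3,
                        varus_bend_mean = 4.5, varus_bend_sd = 1.5,
                        fnc_offset_cranial_mm = 0.4,
                        fnc_offset_proximal_mm = 4.6,
                        observer_sigma_mm = c(0.12, 0.2),
                        n_observers = 2,
                        repeat_sessions_observer1 = 2,
                        within_subject_cv_pct = NULL,
                        seed = NULL) {
  if (n_dogs < 1) stop("`n_dogs` must be >= 1", call. = FALSE)
  if (!all(sides %in% c("left", "right")) || length(sides) < 1) {
    stop("`sides` must be a subset of c('left', 'right')", call. = FALSE)
  }
  sds <- c(torsion_sd, inclination_sd, varus_bend_sd, observer_sigma_mm)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (n_observers < 1 || repeat_sessions_observer1 < 1) {
    stop("`n_observers` and `repeat_sessions_observer1` must be >= 1",
         call. = FALSE)
  }
  if (!is.null(within_subject_cv_pct) && within_subject_cv_pct < 0) {
    stop("`within_subject_cv_pct` must be >= 0", call. = FALSE)
  }
  structure(list(
    n_dogs = as.integer(n_dogs),
    sides = unique(sides),
    torsion_mean = torsion_mean, torsion_sd = torsion_sd,
    inclination_mean = inclination_mean, inclination_sd = inclination_sd,
    varus_bend_mean = varus_bend_mean, varus_bend_sd = varus_bend_sd,
    fnc_offset_cranial_mm = fnc_offset_cranial_mm,
    fnc_offset_proximal_mm = fnc_offset_proximal_mm,
    observer_sigma_mm = rep_len(observer_sigma_mm, n_observers),
    n_observers = as.integer(n_observers),
    repeat_sessions_observer1 = as.integer(repeat_sessions_observer1),
    within_subject_cv_pct = within_subject_cv_pct,
    seed = seed
  ), class = "cohort_spec")
}

#' Read a YAML configuration of phantom / cohort / goniometer blocks
#'
#' Each top-level block (`phantom`, `cohort`, `goniometer`) is optional and
#' holds arguments for the matching constructor.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `phantom`, `cohort`, `goniometer` (those
#'   present in the file), already validated by their constructors.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$phantom)) {
    out$phantom <- do.call(phantom_spec, cfg$phantom)
  }
  if (!is.null(cfg$cohort)) out$cohort <- do.call(cohort_spec, cfg$cohort)
  if (!is.null(cfg$goniometer)) {
    out$goniometer <- do.call(goniometer_model, cfg$goniometer)
  }
  out
}
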