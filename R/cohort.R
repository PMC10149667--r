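#' Simulate a bilateral clinical cohort with observer structure
#'
#' For each dog and side, draws true torsion / inclination / varus-bend
#' parameters from the cohort distributions, builds the corresponding
#' phantom landmarks, and produces one measured angle row per (observer,
#' session): observer 1 measures `repeat_sessions_observer1` times, the
#' other observers once, each measurement using independently perturbed
#' landmarks ([perturb_observer()]). When `within_subject_cv_pct` is set, an
#' explicit multiplicative Gaussian error of that coefficient of variation
#' is additionally applied to every reported angle (independent across
#' sessions), making a known within-subject CV recoverable downstream.
#'
#' @param spec A [cohort_spec()].
#' @param torsion_axis,fia_axis Axis variants passed to [measure_all()].
#' @return A long tibble of measured angles (one row per dog, side,
#'   observer, session) with the true generative parameters attached as the
#'   `"truth"` attribute.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_dogs = 4, seed = 1))
#' dplyr::count(cohort, observer, session)
simulate_cohort <- function(spec, torsion_axis = "td", fia_axis = "td") {
  stopifnot(inherits(spec, "cohort_spec"))
  sessions <- cohort_sessions(spec)
  grid <- tidyr::expand_grid(dog = seq_len(spec$n_dogs), side = spec$sides)

  truth <- grid
  draw <- function(offset, mean, sd) {
    with_local_seed(derive_seed(spec$seed, offset),
                    stats::rnorm(nrow(grid), mean, sd))
  }
  truth$torsion_deg <- draw(1, spec$torsion_mean, spec$torsion_sd)
  truth$inclination_deg <- draw(2, spec$inclination_mean, spec$inclination_sd)
  truth$varus_bend_deg <- draw(3, spec$varus_bend_mean, spec$varus_bend_sd)

  rows <- purrr::pmap(
    list(seq_len(nrow(grid)), truth$torsion_deg, truth$inclination_deg,
         truth$varus_bend_deg, grid$dog, grid$side),
    function(i, tors, incl, bend, dog, side) {
      ph <- phantom_spec(
        nominal_antetorsion_deg = tors,
        nominal_inclination_deg = incl,
        shaft_bend_deg = bend,
        fnc_offset_cranial_mm = spec$fnc_offset_cranial_mm,
        fnc_offset_proximal_mm = spec$fnc_offset_proximal_mm,
        side = side,
        specimen_id = sprintf("dog%03d", dog)
      )
      base_lm <- build_canonical_landmarks(ph)
      purrr::pmap(sessions, function(observer, session, sigma, s_idx) {
        lm <- perturb_observer(
          base_lm, sigma,
          seed = derive_seed(spec$seed, 1000L + i * 16L + s_idx))
        lm$observer <- sprintf("O%d", observer)
        lm$session <- session
        measure_all(lm, torsion_axis = torsion_axis, fia_axis = fia_axis)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()

  if (!is.null(spec$within_subject_cv_pct) &&
      spec$within_subject_cv_pct > 0) {
    cvf <- spec$within_subject_cv_pct / 100
    angle_cols <- c("fta_nc", "fta_nbc", "fia_nc", "fia_nbc",
                    "fva_pd", "fva_td")
    rows[angle_cols] <- with_local_seed(
      derive_seed(spec$seed, 4L),
      lapply(rows[angle_cols],
             function(v) v * (1 + stats::rnorm(length(v), 0, cvf))))
  }
  attr(rows, "truth") <- truth
  rows
}

cohort_sessions <- function(spec) {
  obs <- integer(0); ses <- integer(0)
  for (s in seq_len(spec$repeat_sessions_observer1)) {
    obs <- c(obs, 1L); ses <- c(ses, s)
  }
  if (spec$n_observers > 1) {
    obs <- c(obs, 2:spec$n_observers)
    ses <- c(ses, rep(1L, spec$n_observers - 1L))
  }
  tibble::tibble(observer = obs, session = ses,
                 sigma = spec$observer_sigma_mm[obs],
                 s_idx = seq_along(obs))
}

#' Simulate duplicate measurements with a known within-subject CV
#'
#' Generates a long repeated-measures table where each subject's true value
#' is drawn from `N(mean, between_sd)` and each of the k replicates is the
#' true value times `(1 + N(0, cv/100))` — i.e. the within-subject SD is
#' proportional to the subject level, so Bland's RMS CV estimator targets
#' exactly `within_cv_pct`.
#'
#' @param n_subjects Number of subjects.
#' @param k Replicates per subject (default 2).
#' @param mean,between_sd Between-subject distribution of true values.
#' @param within_cv_pct Injected within-subject CV, percent.
#' @param seed Optional integer seed.
#' @return Tibble with columns `subject`, `replicate`, `value`.
#' @export
simulate_repeated_measures <- function(n_subjects, k = 2, mean = 23,
                                       between_sd = 3, within_cv_pct = 5,
                                       seed = NULL) {
  stopifnot(n_subjects >= 1, k >= 2, within_cv_pct >= 0)
  with_local_seed(seed, {
    truth <- stats::rnorm(n_subjects, mean, between_sd)
    tibble::tibble(
      subject = rep(seq_len(n_subjects), each = k),
      replicate = rep(seq_len(k), n_subjects),
      value = rep(truth, each = k) *
        (1 + stats::rnorm(n_subjects * k, 0, within_cv_pct / 100))
    )
  })
}
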