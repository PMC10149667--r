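#' Run the phantom accuracy experiment
#'
#' For each preset hinge angle: builds the hinged phantom, applies a random
#' rigid pose (the bone's arbitrary position in the scanner), perturbs the
#' landmarks with observer noise, measures FTA-NBC through the full frame
#' construction, simulates the goniometer reference reading of the true
#' torsion, and finally compares the paired (goniometer, software)
#' measurements with Bland-Altman and Passing-Bablok statistics.
#'
#' @param phantom A [phantom_spec()] (its `hinge_angle_deg` is overridden by
#'   `presets`).
#' @param presets Hinge angles in degrees (>= 3 values).
#' @param goniometer A [goniometer_model()] for the reference readings.
#' @param observer_sigma_mm Landmark placement noise SD, mm.
#' @param pose Apply a random rigid pose per preset (default `TRUE`).
#' @param seed Top-level integer seed.
#' @return Object of class `accuracy_experiment`: `measurements` (tibble
#'   with `hinge_angle_deg`, `preset_torsion_deg`, `goniometer_deg`,
#'   `software_deg`), `bland_altman`, `passing_bablok`, and `tau0` (the
#'   baseline antetorsion).
#' @export
#' @examples
#' run_accuracy_experiment(observer_sigma_mm = 0, seed = 1)
run_accuracy_experiment <- function(phantom = phantom_spec(),
                                    presets = c(-90, -50, -40, -30, -20,
                                                -10, 0, 10, 20, 30, 40,
                                                50, 90),
                                    goniometer = goniometer_model(),
                                    observer_sigma_mm = 0,
                                    pose = TRUE,
                                    seed = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(goniometer, "goniometer_model"))
  if (length(presets) < 3) {
    stop("insufficient data: need at least 3 presets", call. = FALSE)
  }
  tau0 <- phantom$nominal_antetorsion_deg
  software <- vapply(seq_along(presets), function(i) {
    lm <- build_canonical_landmarks(phantom)
    lm <- apply_hinge(lm, presets[i], phantom$hinge_level_fraction)
    if (pose) {
      lm <- apply_pose(lm, random_rotation(derive_seed(seed, 100L + i)),
                       with_local_seed(derive_seed(seed, 200L + i),
                                       stats::rnorm(3, 0, 50)))
    }
    if (observer_sigma_mm > 0) {
      lm <- perturb_observer(lm, observer_sigma_mm,
                             seed = derive_seed(seed, 300L + i))
    }
    femoral_torsion(lm, "NBC")
  }, numeric(1))
  preset_torsion <- tau0 + presets
  gonio <- simulate_goniometer(preset_torsion, goniometer,
                               seed = derive_seed(seed, 400L))
  meas <- tibble::tibble(hinge_angle_deg = presets,
                         preset_torsion_deg = preset_torsion,
                         goniometer_deg = gonio,
                         software_deg = software)
  structure(list(
    measurements = meas,
    bland_altman = bland_altman(meas, goniometer_deg, software_deg),
    passing_bablok = passing_bablok(meas, goniometer_deg, software_deg),
    tau0 = tau0
  ), class = "accuracy_experiment")
}

#' @export
print.accuracy_experiment <- function(x, ...) {
  cat(sprintf("Phantom accuracy experiment (%d presets, tau0 = %.1f deg)\n",
              nrow(x$measurements), x$tau0))
  print(x$bland_altman)
  print(x$passing_bablok)
  invisible(x)
}

angle_labels <- c(fta_nbc = "FTA-NBC", fta_nc = "FTA-NC",
                  fia_nbc = "FIA-NBC", fia_nc = "FIA-NC",
                  fva_td = "FVA-td", fva_pd = "FVA-pd")

#' Run the cohort precision experiment
#'
#' Simulates the cohort ([simulate_cohort()]), forms duplicate tables per
#' angle variant and side for the intraobserver pairing (observer 1, session
#' 1 vs session 2) and the interobserver pairing (observer 1 session 1 vs
#' observer 2), and summarizes each as grand mean, within-subject SD
#' (`sqrt(mean(s_i^2))`), Bland's CV for repeated measurements, and its
#' rating. Also reports the published-style difference-of-means summaries
#' (NBC minus NC for torsion and inclination, pd minus td for varus).
#'
#' @param cohort A [cohort_spec()].
#' @param ... Passed to [simulate_cohort()].
#' @return Object of class `precision_experiment`: `measurements` (long
#'   per-session angles), `summary` (one row per angle x side, intra and
#'   inter columns, the published table's shape), and `diffs`
#'   (difference-of-means rows).
#' @export
#' @examples
#' run_precision_experiment(cohort_spec(n_dogs = 6, seed = 1))
run_precision_experiment <- function(cohort = cohort_spec(), ...) {
  stopifnot(inherits(cohort, "cohort_spec"))
  meas <- simulate_cohort(cohort, ...)
  long <- meas |>
    tidyr::pivot_longer(dplyr::all_of(names(angle_labels)),
                        names_to = "angle_var", values_to = "value") |>
    dplyr::mutate(angle = angle_labels[.data$angle_var])

  pairing_tbl <- function(df, pairing) {
    keep <- if (pairing == "intra") {
      df$observer == "O1" & df$session %in% c(1L, 2L)
    } else {
      (df$observer == "O1" & df$session == 1L) | df$observer == "O2"
    }
    df[keep, ]
  }
  summarize_one <- function(df) {
    fit <- cv_repeated(df, subject = specimen_id, value = value)
    groups <- split(df$value, df$specimen_id)
    tibble::tibble(
      mean = mean(df$value),
      sd = sqrt(mean(vapply(groups, stats::var, numeric(1)))),
      cv = fit$cv_percent,
      rating = fit$rating
    )
  }
  summary <- tidyr::expand_grid(
    angle = unname(angle_labels),
    side = cohort$sides
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(res = list(purrr::map(
      c(intra = "intra", inter = "inter"),
      \(p) summarize_one(pairing_tbl(
        long[long$angle == .data$angle & long$side == .data$side, ], p))
    ))) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      mean_intra = purrr::map_dbl(.data$res, \(r) r$intra$mean),
      sd_intra = purrr::map_dbl(.data$res, \(r) r$intra$sd),
      cv_intra = purrr::map_dbl(.data$res, \(r) r$intra$cv),
      rating_intra = purrr::map_chr(.data$res, \(r) r$intra$rating),
      mean_inter = purrr::map_dbl(.data$res, \(r) r$inter$mean),
      sd_inter = purrr::map_dbl(.data$res, \(r) r$inter$sd),
      cv_inter = purrr::map_dbl(.data$res, \(r) r$inter$cv),
      rating_inter = purrr::map_chr(.data$res, \(r) r$inter$rating)
    ) |>
    dplyr::select(-"res")

  diff_pairs <- tibble::tribble(
    ~angle_a, ~angle_b,
    "FTA-NBC", "FTA-NC",
    "FIA-NBC", "FIA-NC",
    "FVA-pd", "FVA-td"
  )
  diffs <- tidyr::expand_grid(diff_pairs, side = cohort$sides,
                              pairing = c("intra", "inter")) |>
    dplyr::rowwise() |>
    dplyr::mutate(diff_deg = diff_of_means(summary, .data$angle_a,
                                           .data$angle_b, .data$side,
                                           .data$pairing)) |>
    dplyr::ungroup()

  structure(list(measurements = meas, summary = summary, diffs = diffs,
                 cohort = cohort),
            class = "precision_experiment")
}

#' @export
print.precision_experiment <- function(x, ...) {
  cat(sprintf(
    "Cohort precision experiment: %d dogs, %d sides, %d measurement rows\n",
    x$cohort$n_dogs, length(x$cohort$sides), nrow(x$measurements)))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Difference of printed-precision means between two angle variants
#'
#' Takes a Table-2-shaped summary (columns `angle`, `side`, `mean_intra`,
#' `mean_inter` — either [load_table2_fixture()] or the `summary` of
#' [run_precision_experiment()]) and returns the difference of the two
#' variants' means for one side and pairing, rounded to 2 decimal places.
#'
#' @param summary Summary tibble.
#' @param angle_a,angle_b Angle labels, e.g. `"FTA-NBC"`, `"FTA-NC"`.
#' @param side `"left"` or `"right"`.
#' @param pairing `"intra"` or `"inter"`.
#' @return `round(mean_a - mean_b, 2)` in degrees.
#' @export
#' @examples
#' diff_of_means(load_table2_fixture(), "FTA-NBC", "FTA-NC", "right",
#'               "intra")  # 3.51
diff_of_means <- function(summary, angle_a, angle_b, side,
                          pairing = c("intra", "inter")) {
  pairing <- match.arg(pairing)
  col <- paste0("mean_", pairing)
  pick <- function(a) {
    row <- summary[summary$angle == a & summary$side == side, ]
    if (nrow(row) != 1) {
      stop("missing variant: no unique row for angle '", a, "', side '",
           side, "'", call. = FALSE)
    }
    row[[col]]
  }
  round(pick(angle_a) - pick(angle_b), 2)
}
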