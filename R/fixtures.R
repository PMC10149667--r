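TABLE1_MD5 <- "469ebda3f9d0ebcfbb15699072d25503"
TABLE2_MD5 <- "df6ec9ee490689e8b8580133881b351e"

fixture_path <- function(file, md5) {
  path <- system.file("extdata", file, package = "femur3d", mustWork = TRUE)
  if (unname(tools::md5sum(path)) != md5) {
    stop("fixture integrity error: checksum mismatch for ", file,
         call. = FALSE)
  }
  path
}

#' Packaged phantom accuracy-study pairs
#'
#' The 13 published (preset, CT-measured) femoral torsion pairs from the
#' torsional-deformity phantom study: hinge settings from -90 to +90 degrees
#' about the physiological +21.5 degree baseline, the goniometer-read preset
#' torsion, and the software-measured FTA-NBC, stored at the printed 0.1
#' degree precision. The file checksum is verified on load.
#'
#' @return Tibble with columns `hinge_deg`, `goniometer_deg`,
#'   `software_deg` (13 rows).
#' @export
#' @examples
#' bland_altman(load_table1_fixture(), goniometer_deg, software_deg)
load_table1_fixture <- function() {
  out <- readr::read_csv(fixture_path("table1_torsion_pairs.csv",
                                      TABLE1_MD5),
                         show_col_types = FALSE)
  stopifnot(nrow(out) == 13)
  out
}

#' Packaged clinical agreement summary table
#'
#' The published per-angle, per-side intra- and interobserver agreement
#' summary for the 34-dog bilateral cohort: grand mean (degrees),
#' within-subject SD and coefficient of variation for repeated measurements
#' (percent), for the six angle variants on both sides. Used by
#' [diff_of_means()] for the reported between-variant mean differences.
#'
#' @return Tibble with columns `angle`, `side`, `mean_intra`, `sd_intra`,
#'   `cv_intra`, `mean_inter`, `sd_inter`, `cv_inter` (12 rows).
#' @export
load_table2_fixture <- function() {
  out <- readr::read_csv(fixture_path("table2_agreement.csv", TABLE2_MD5),
                         show_col_types = FALSE)
  stopifnot(nrow(out) == 12)
  out
}
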