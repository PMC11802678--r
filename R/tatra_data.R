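tatra_csv <- function(name) {
  path <- system.file("extdata", name, package = "oxstab", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference High Tatras ozonation experiment: exposure doses
#'
#' Six-point cumulative ozone doses (ppm) for the two sampling zones of the
#' bundled High Tatras conifer ozonation experiment: the alpine treeline
#' ecotone (ATE, ~1600 m) and the foothill zone (FH, ~830 m). Series 1 is the
#' ambient 2023 growing-season sum; series 2-6 add chamber ozonation of 1 to
#' 10 h at ~150 ppm.
#'
#' @return data.frame with columns \code{zone}, \code{series_index},
#'   \code{exposure_h}, \code{sum_o3_ppm}.
#' @export
tatra_doses <- function() tatra_csv("ozonation_doses.csv")

#' Reference High Tatras ozonation experiment: injury indices
#'
#' Electrolyte-leakage injury indices \code{INX(n)} (percent) per species and
#' zone; series 0 is the exponential-fit zero-ozone baseline, series 1 the
#' ambient-season response, series 2-6 graduated chamber ozonation.
#'
#' @return data.frame with columns \code{zone}, \code{species},
#'   \code{series_index}, \code{inx_pct}.
#' @export
tatra_injury <- function() tatra_csv("injury_indices.csv")

#' Reference High Tatras ozonation experiment: oxidative stability
#'
#' \code{OxS(n)} values per species and zone for series 1-6.
#'
#' @return data.frame with columns \code{zone}, \code{species},
#'   \code{series_index}, \code{oxs}.
#' @export
tatra_oxs <- function() tatra_csv("oxidative_stability.csv")

#' Reference High Tatras ozonation experiment: critical doses
#'
#' Published cumulative doses \code{sumO3(OxS)} (ppm) at the OxS = -0.05
#' threshold per species and zone.
#'
#' @return data.frame with columns \code{zone}, \code{species},
#'   \code{sum_o3_oxs_ppm}.
#' @export
tatra_critical_doses <- function() tatra_csv("critical_doses.csv")

#' Reference High Tatras ozonation experiment: flux summary
#'
#' Seasonal average ozone concentrations and modelled POD0 under ambient
#' conditions and under the flat critical-level projection, per species and
#' zone.
#'
#' @return data.frame with columns \code{zone}, \code{species},
#'   \code{avg_o3_ambient_ppb}, \code{pod0_ambient_mmol_m2},
#'   \code{avg_o3_cl_ppb}, \code{pod0_cl_mmol_m2}.
#' @export
tatra_flux_summary <- function() tatra_csv("flux_summary.csv")

#' Reference High Tatras growing seasons (2023)
#'
#' The growing seasons detected under the 5 degC rule at the two zones in
#' 2023: June 1 - September 30 at the alpine treeline ecotone (2928 h) and
#' May 1 - September 30 at the foothill site (3672 h).
#'
#' @return named list of [growing_season()] objects (\code{ATE}, \code{FH}).
#' @export
tatra_growing_seasons <- function() {
  list(ATE = growing_season("2023-06-01", "2023-09-30"),
       FH = growing_season("2023-05-01", "2023-09-30"))
}
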