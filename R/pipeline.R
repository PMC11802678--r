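#' Pipeline configuration
#'
#' Collects the inputs and numeric settings for [run_full_pipeline()]. Each
#' tabular input may be given as a data.frame or a CSV path (schemas as in
#' the respective readers). Either \code{conductivity} (raw EL assays) or
#' \code{injury} (pre-computed indices) must be supplied.
#'
#' @param conductivity conductivity table (see [read_conductivity_csv()]) or
#'   path, or \code{NULL}.
#' @param injury injury-index table with columns \code{zone}, \code{species},
#'   \code{series_index} (1..6), \code{inx_pct}, or path, or \code{NULL}.
#' @param doses dose table with columns \code{zone}, \code{series_index},
#'   \code{sum_o3_ppm}, or path. Default: the bundled High Tatras doses.
#' @param env named list (by zone) of hourly environmental series or CSV
#'   paths; zones without a series skip the flux stage.
#' @param peaks optional GC-MS peak table or path; enables the composition
#'   stage.
#' @param params optional named list (by species) of [flux_params()]; species
#'   not listed fall back to their named preset, or the boreal-conifer
#'   default.
#' @param degree polynomial degree of the dose-response fit, >= 1.
#' @param threshold OxS threshold in (-1, 0), default -0.05.
#' @param min_coverage ozone coverage floor for seasonal sums, default 0.9.
#' @param daylight_rad daylight radiation threshold, W m-2, default 50.
#' @param out_dir optional output directory for CSV/JSON reports.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(conductivity = NULL, injury = NULL,
                            doses = NULL, env = list(), peaks = NULL,
                            params = list(), degree = 2, threshold = -0.05,
                            min_coverage = 0.9, daylight_rad = 50,
                            out_dir = NULL) {
  if (is.null(conductivity) && is.null(injury)) {
    stop("supply either a conductivity table or an injury-index table")
  }
  if (!(threshold > -1 && threshold < 0)) stop("threshold must lie in (-1, 0)")
  if (degree < 1) stop("degree must be >= 1")
  cfg <- list(conductivity = conductivity, injury = injury, doses = doses,
              env = env, peaks = peaks, params = params, degree = degree,
              threshold = threshold, min_coverage = min_coverage,
              daylight_rad = daylight_rad, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

load_table <- function(x, reader) {
  if (is.character(x)) reader(x) else x
}

preset_key <- function(species) tolower(gsub("[ .]+", "_", species))

atomic_write_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
}

#' Run the full critical-level derivation pipeline
#'
#' Executes the stages end to end: injury indices from conductivity assays
#' (or pre-computed indices), exponential zero-ozone baselines, oxidative
#' stability, polynomial dose-response fits inverted at the OxS threshold,
#' growing-season detection and exposure conversion per zone, the stomatal
#' flux model (ambient POD0 and flat-profile CL(OxS)), tolerance
#' utilisation, and (when a peak table is supplied) GC-MS class composition
#' with per-class ANOVA.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class \code{oxstab_report} with elements \code{injury},
#'   \code{baselines}, \code{oxs}, \code{summary} (one row per species x
#'   zone with presentation and full-precision columns), \code{seasons},
#'   \code{composition} and \code{anova} (or \code{NULL}). When
#'   \code{cfg$out_dir} is set the tables are also written as CSV plus a
#'   machine-readable JSON report; files are written atomically.
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  injury <- if (!is.null(cfg$conductivity)) {
    m <- load_table(cfg$conductivity, read_conductivity_csv)
    if (nrow(m) == 0) stop("schema error: empty conductivity table")
    ii <- injury_indices(m)
    data.frame(zone = ii$zone, species = ii$species,
               series_index = ii$series_index, inx_pct = ii$inx)
  } else {
    ij <- load_table(cfg$injury, function(p) utils::read.csv(p, stringsAsFactors = FALSE))
    req <- c("zone", "species", "series_index", "inx_pct")
    miss <- setdiff(req, names(ij))
    if (length(miss) || nrow(ij) == 0) {
      stop("schema error in injury table: ",
           if (nrow(ij) == 0) "no rows" else paste("missing", paste(miss, collapse = ", ")))
    }
    ij
  }
  doses <- if (is.null(cfg$doses)) tatra_doses() else {
    load_table(cfg$doses, function(p) utils::read.csv(p, stringsAsFactors = FALSE))
  }
  if (!all(c("zone", "series_index", "sum_o3_ppm") %in% names(doses))) {
    stop("schema error in dose table: need zone, series_index, sum_o3_ppm")
  }

  # seasons and exposure per zone with an hourly series
  seasons <- list(); zone_stats <- list()
  for (z in names(cfg$env)) {
    env <- load_table(cfg$env[[z]], read_env_csv)
    gs <- detect_growing_season(env)
    sum_amb <- cumulative_exposure(env, gs, min_coverage = cfg$min_coverage)
    zone_stats[[z]] <- list(env = env, gs = gs, sum_ambient = sum_amb,
                            avg_ambient = sum_to_avg(sum_amb, gs))
    seasons[[z]] <- gs
  }

  obs <- injury[injury$series_index >= 1, ]
  key <- interaction(obs$zone, obs$species, drop = TRUE, sep = "\r")
  baselines <- list(); oxs_rows <- list(); summary_rows <- list()
  for (g in split(obs, key)) {
    z <- g$zone[1]; sp <- g$species[1]
    d <- doses[doses$zone == z, ]
    d <- d[match(g$series_index, d$series_index), "sum_o3_ppm"]
    if (anyNA(d)) stop("dose table lacks series for zone ", z)
    ord <- order(d)
    fit <- fit_exponential_baseline(d[ord], g$inx_pct[ord])
    oxs <- compute_oxs(g$inx_pct[ord], fit$a)
    dr <- fit_dose_response(d[ord], oxs, degree = cfg$degree)
    cd <- invert_threshold(dr, threshold = cfg$threshold)
    baselines[[length(baselines) + 1L]] <- data.frame(
      zone = z, species = sp, inx0 = round(fit$a, 1), inx0_full = fit$a,
      b_per_ppm = fit$b, r = fit$r, p = fit$p)
    oxs_rows[[length(oxs_rows) + 1L]] <- data.frame(
      zone = z, species = sp, series_index = g$series_index[ord],
      sum_o3_ppm = d[ord], oxs = round(oxs, 2), oxs_full = oxs)
    zs <- zone_stats[[z]]
    avg_cl <- pod_amb <- pod_cl <- util <- NA_real_
    if (!is.null(zs)) {
      avg_cl <- sum_to_avg(cd$sum_o3_oxs, zs$gs)
      p <- if (!is.null(cfg$params[[sp]])) cfg$params[[sp]] else {
        key_sp <- preset_key(sp)
        tryCatch(flux_params(species = key_sp),
                 error = function(e) flux_params())
      }
      pod_amb <- compute_pod(zs$env, p, zs$gs, y = 0,
                             daylight_rad = cfg$daylight_rad)
      pod_cl <- project_cl_oxs(avg_cl, zs$env, p, zs$gs)
      util <- tolerance_utilisation(pod_amb, pod_cl)
    }
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      zone = z, species = sp,
      inx0 = round(fit$a, 1), inx0_full = fit$a,
      sum_o3_oxs_ppm = round(cd$sum_o3_oxs, 1),
      sum_o3_oxs_ppm_full = cd$sum_o3_oxs,
      extrapolated = cd$extrapolated,
      avg_o3_ambient_ppb = if (is.null(zs)) NA_real_ else round(zs$avg_ambient, 1),
      avg_o3_cl_ppb = round(avg_cl, 1), avg_o3_cl_ppb_full = avg_cl,
      pod0_ambient_mmol_m2 = pod_amb, pod0_cl_mmol_m2 = pod_cl,
      utilisation_pct = round(util, 1), utilisation_pct_full = util)
  }

  composition <- anova_tables <- NULL
  if (!is.null(cfg$peaks)) {
    pk <- load_table(cfg$peaks, read_peak_table)
    composition <- aggregate_classes(normalise_peak_areas(pk))
    anova_tables <- lapply(
      setdiff(unique(composition$class), character(0)),
      function(cl) {
        sub <- composition[composition$class == cl, ]
        one_way_anova(sub$pct, sub$ozonation_category)
      })
    names(anova_tables) <- unique(composition$class)
  }

  report <- list(
    injury = injury,
    baselines = do.call(rbind, baselines),
    oxs = do.call(rbind, oxs_rows),
    summary = do.call(rbind, summary_rows),
    seasons = seasons,
    composition = composition,
    anova = anova_tables,
    settings = list(degree = cfg$degree, threshold = cfg$threshold,
                    min_coverage = cfg$min_coverage,
                    daylight_rad = cfg$daylight_rad)
  )
  class(report) <- "oxstab_report"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    atomic_write_csv(report$baselines, file.path(cfg$out_dir, "baselines.csv"))
    atomic_write_csv(report$oxs, file.path(cfg$out_dir, "oxs.csv"))
    atomic_write_csv(report$summary, file.path(cfg$out_dir, "summary.csv"))
    json <- list(settings = report$settings,
                 seasons = lapply(seasons, function(g) {
                   list(start = format(g$start_date), end = format(g$end_date),
                        hours = g$hours)
                 }),
                 summary = report$summary)
    tmp <- tempfile(tmpdir = cfg$out_dir)
    jsonlite::write_json(json, tmp, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    file.rename(tmp, file.path(cfg$out_dir, "report.json"))
  }
  report
}

#' @export
print.oxstab_report <- function(x, ...) {
  cat("oxstab pipeline report\n")
  cat(sprintf("  %d species x zone series; dose-response degree %d, OxS threshold %.2f\n",
              nrow(x$summary), x$settings$degree, x$settings$threshold))
  cols <- c("zone", "species", "inx0", "sum_o3_oxs_ppm", "avg_o3_cl_ppb",
            "pod0_ambient_mmol_m2", "pod0_cl_mmol_m2", "utilisation_pct")
  print(x$summary[, intersect(cols, names(x$summary))], row.names = FALSE)
  invisible(x)
}
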