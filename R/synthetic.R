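#' Evaluate code with a local, restorable RNG state
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's
#' random-number state afterwards, so generators leave no global trace.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic-data generators
#'
#' Collects the parameters of the seeded generators that emulate the study
#' conditions: a six-point ozonation experiment (ambient growing-season
#' exposure plus chamber ozonation at ~150 ppm for 1, 3, 5, 7 and 10 h),
#' exponential injury response \eqn{INX(x) = a e^{bx}} with multiplicative
#' lognormal measurement noise, hourly mountain-site meteorology with either
#' a flat (alpine) or diurnal (foothill) ozone profile, and four-class
#' GC-MS terpenoid peak tables.
#'
#' @param seed integer seed; fixed seed implies bit-identical outputs.
#' @param zone_profile \code{"alpine-flat"} (treeline: flat diurnal ozone,
#'   June-September season) or \code{"foothill-diurnal"} (diurnal ozone
#'   cycle, May-September season).
#' @param o3_mean seasonal mean ozone, ppb; default 52.7 (alpine) / 27.5
#'   (foothill).
#' @param o3_diurnal_amplitude diurnal ozone amplitude, ppb; 0 for the
#'   alpine profile, default 15 for the foothill profile.
#' @param injury_a baseline injury \code{a}, percent; default 10.
#' @param injury_b injury rate \code{b}, per ppm; default 8e-4.
#' @param noise_sd relative measurement noise (lognormal sigma); default 0.05.
#' @param exposure_times chamber exposure times, hours.
#' @param chamber_concentration chamber ozone concentration, ppm (dose rate
#'   per hour of exposure); default 150.
#' @param chamber_sd relative lognormal variability of the effective chamber
#'   dose per series; default 0.05.
#' @param n_replicates conductivity replicates per series member; default 3.
#' @param species,zone labels attached to generated experiment tables.
#' @param n_samples_per_category samples per ozonation category in generated
#'   peak tables; default 6.
#' @param composition_effect relative decrease of the monoterpene share per
#'   ozonation step A -> B -> C (0 = null generator); default 0.25.
#' @param dirichlet_conc total Dirichlet concentration controlling
#'   between-sample composition variability; default 60.
#' @return object of class \code{synthetic_config} (named list, with derived
#'   fields \code{gs_start_month}, \code{gs_end_month} and \code{zone}).
#' @export
synthetic_config <- function(seed = 1,
                             zone_profile = c("alpine-flat", "foothill-diurnal"),
                             o3_mean = NULL, o3_diurnal_amplitude = NULL,
                             injury_a = 10, injury_b = 8e-4, noise_sd = 0.05,
                             exposure_times = c(1, 3, 5, 7, 10),
                             chamber_concentration = 150, chamber_sd = 0.05,
                             n_replicates = 3,
                             species = "Pinus mugo", zone = NULL,
                             n_samples_per_category = 6,
                             composition_effect = 0.25,
                             dirichlet_conc = 60) {
  zone_profile <- match.arg(zone_profile)
  alpine <- zone_profile == "alpine-flat"
  if (is.null(o3_mean)) o3_mean <- if (alpine) 52.7 else 27.5
  if (is.null(o3_diurnal_amplitude)) o3_diurnal_amplitude <- if (alpine) 0 else 15
  if (alpine && o3_diurnal_amplitude != 0) {
    stop("alpine-flat profile requires zero diurnal ozone amplitude")
  }
  if (is.null(zone)) zone <- if (alpine) "ATE" else "FH"
  cfg <- list(seed = as.integer(seed), zone_profile = zone_profile,
              o3_mean = o3_mean, o3_diurnal_amplitude = o3_diurnal_amplitude,
              injury_a = injury_a, injury_b = injury_b, noise_sd = noise_sd,
              exposure_times = exposure_times,
              chamber_concentration = chamber_concentration,
              chamber_sd = chamber_sd, n_replicates = n_replicates,
              species = species, zone = zone,
              gs_start_month = if (alpine) 6L else 5L, gs_end_month = 9L,
              n_samples_per_category = n_samples_per_category,
              composition_effect = composition_effect,
              dirichlet_conc = dirichlet_conc)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate an hourly environmental series for one site-year
#'
#' Hourly air temperature (seasonal + diurnal harmonics plus bounded noise),
#' global radiation (seasonal daylight sinusoid), relative humidity with the
#' derived vapour pressure deficit, and ozone
#' \eqn{O_3 = mean + amplitude \cdot \sin(2\pi(h-15)/24)} truncated at 0.
#' The temperature field is constructed so the 5 degC growing-season rule
#' recovers the profile's season: each month outside the configured window
#' receives one all-cold day, and days inside the window are kept above the
#' rule's trigger.
#'
#' @param cfg a [synthetic_config()].
#' @param year calendar year, default 2023.
#' @return hourly data.frame with columns \code{timestamp}, \code{t_air_c},
#'   \code{o3_ppb}, \code{glob_rad_wm2}, \code{rh_pct}, \code{vpd_kpa}.
#' @export
generate_env_series <- function(cfg, year = 2023) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 101L, {
    start <- as.POSIXct(paste0(year, "-01-01 00:00:00"), tz = "UTC")
    end <- as.POSIXct(paste0(year, "-12-31 23:00:00"), tz = "UTC")
    ts <- seq(start, end, by = "1 hour")
    doy <- as.integer(format(ts, "%j"))
    hr <- as.integer(format(ts, "%H"))
    mon <- as.integer(format(ts, "%m"))
    mday <- as.integer(format(ts, "%d"))
    alpine <- cfg$zone_profile == "alpine-flat"
    t_mean <- if (alpine) 3 else 7
    t_seas <- if (alpine) 10 else 11
    t_diur <- 4
    t <- t_mean + t_seas * cos(2 * pi * (doy - 202) / 365.25) +
      t_diur * sin(2 * pi * (hr - 9) / 24) +
      stats::runif(length(ts), -0.5, 0.5)
    in_gs <- mon >= cfg$gs_start_month & mon <= cfg$gs_end_month
    # keep every growing-season day clear of the all-cold rule
    for (d in unique(doy[in_gs])) {
      i <- which(doy == d)
      if (max(t[i]) < 6) t[i] <- t[i] + (6 - max(t[i]))
    }
    # one all-cold day (the 15th) in every month outside the season window
    cold <- !unique(mon) %in% cfg$gs_start_month:cfg$gs_end_month
    for (m in unique(mon)[cold]) {
      i <- which(mon == m & mday == 15L)
      t[i] <- pmin(t[i], 3)
    }
    rad_peak <- 450 + 400 * cos(2 * pi * (doy - 172) / 365.25)
    rad <- pmax(0, rad_peak * sin(pi * (hr - 6) / 12)) *
      (hr >= 6 & hr <= 18)
    rad <- pmax(0, rad + stats::runif(length(ts), -10, 10) * (rad > 0))
    rh <- pmin(100, pmax(25, 75 - 20 * cos(2 * pi * (hr - 15) / 24) +
                           stats::runif(length(ts), -3, 3)))
    es <- 0.611 * exp(17.502 * t / (t + 240.97))
    vpd <- pmax(0, es * (1 - rh / 100))
    # diurnal term peaks at 15:00 and sums to zero over each 24 h day
    o3 <- pmax(0, cfg$o3_mean +
                 cfg$o3_diurnal_amplitude * cos(2 * pi * (hr - 15) / 24))
    data.frame(timestamp = ts, t_air_c = t, o3_ppb = o3,
               glob_rad_wm2 = rad, rh_pct = rh, vpd_kpa = vpd)
  })
}

gs_days_for <- function(cfg, year = 2023) {
  first <- as.Date(sprintf("%d-%02d-01", year, cfg$gs_start_month))
  last_first <- as.Date(sprintf("%d-%02d-01", year, cfg$gs_end_month))
  last <- seq(last_first, by = "1 month", length.out = 2)[2] - 1
  as.integer(last - first) + 1L
}

#' Generate a six-point ozonation dose series
#'
#' Element 1 is the ambient seasonal sum (seasonal mean concentration x
#' season hours / 1000); elements 2..6 add the chamber dose
#' (chamber concentration x exposure time), with optional lognormal
#' variability of the effective chamber rate per series member.
#'
#' @param cfg a [synthetic_config()].
#' @param year calendar year defining the season length.
#' @return numeric vector of six strictly increasing sumO3 values, ppm.
#' @export
generate_ozonation_series <- function(cfg, year = 2023) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 202L, {
    ambient <- cfg$o3_mean * 24 * gs_days_for(cfg, year) / 1000
    rate <- cfg$chamber_concentration
    if (cfg$chamber_sd > 0) {
      rate <- rate * stats::rlnorm(length(cfg$exposure_times),
                                   meanlog = 0, sdlog = cfg$chamber_sd)
    }
    doses <- c(ambient, ambient + rate * cfg$exposure_times)
    if (is.unsorted(doses, strictly = TRUE)) doses <- sort(doses)
    doses
  })
}

#' Generate a conductivity experiment with known injury truth
#'
#' Inverse construction for pipeline recovery tests: the true injury follows
#' \eqn{INX(x) = a e^{bx}}; each replicate observes the truth under
#' multiplicative lognormal noise, and conductivities are built so that
#' [injury_index()] returns exactly the noisy index (blanks fixed at 2
#' uS/cm, post-autoclave span fixed at 100 uS/cm, pre-autoclave solution
#' solved for).
#'
#' @param cfg a [synthetic_config()].
#' @param year calendar year defining the ambient season.
#' @return list with \code{doses} (ppm) and \code{measurements}
#'   (conductivity data.frame accepted by [injury_indices()]).
#' @export
generate_conductivity_experiment <- function(cfg, year = 2023) {
  stopifnot(inherits(cfg, "synthetic_config"))
  doses <- generate_ozonation_series(cfg, year)
  with_seed(cfg$seed + 303L, {
    rows <- expand.grid(rep = seq_len(cfg$n_replicates),
                        series_index = seq_along(doses))
    truth <- cfg$injury_a * exp(cfg$injury_b * doses[rows$series_index])
    noisy <- truth
    if (cfg$noise_sd > 0) {
      noisy <- truth * stats::rlnorm(nrow(rows), 0, cfg$noise_sd)
    }
    noisy <- pmin(noisy, 100)
    data.frame(
      sample_id = sprintf("%s_%s_n%d_r%d", cfg$zone,
                          gsub(" ", "_", cfg$species),
                          rows$series_index, rows$rep),
      species = cfg$species, zone = cfg$zone,
      series_index = rows$series_index,
      c_blank_fresh = 2, c_fresh = 2 + noisy,
      c_blank_auto = 2, c_auto = 102
    ) -> measurements
    list(doses = doses, measurements = measurements)
  })
}

synthetic_compounds <- function() {
  data.frame(
    retention_index = c(1011, 1042, 1079, 1213, 1246, 1354, 1442, 1506,
                        1537, 1544, 2381, 2845, 3271),
    compound = c("gamma-terpinene", "alpha-thujene", "alpha-pinene",
                 "benzoic acid", "coumaran", "delta-elemene",
                 "alpha-cubebene", "germacrene D", "gamma-cadinene",
                 "delta-cadinene", "dehydroabietic acid methyl ester",
                 "dehydroisoandrosterone acetate", "alpha-tocopherol"),
    formula = c("C10H16", "C10H16", "C10H16", "C7H6O2", "C8H8O",
                "C15H24", "C15H24", "C15H24", "C15H24", "C15H24",
                "C21H30O3", "C21H30O3", "C29H50O2"),
    class = c(rep("monoterpene", 3), rep("oxidation_C7_C8", 2),
              rep("sesquiterpene", 5), rep("oxidation_C20plus", 3)),
    within_class_weight = c(0.15, 0.15, 0.70, 0.80, 0.20,
                            0.10, 0.10, 0.35, 0.20, 0.25,
                            0.55, 0.40, 0.05)
  )
}

#' Generate a GC-MS peak table across ozonation categories
#'
#' Samples class proportions from a Dirichlet distribution (via gamma
#' variates) with category effects: the monoterpene share decreases with
#' ozonation (A ambient -> B 3 h -> C 10 h) in favour of C7-C8 oxidation
#' products, while the sesquiterpene share stays stable. Class shares are
#' split into the 13 reference compounds with fixed within-class weights.
#' Setting \code{composition_effect = 0} gives a null generator for type-I
#' error checks.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame peak table with columns \code{sample_id},
#'   \code{species}, \code{zone}, \code{ozonation_category},
#'   \code{retention_index}, \code{compound}, \code{formula}, \code{area}.
#' @export
generate_peak_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed + 404L, {
    comp <- synthetic_compounds()
    base_share <- c(monoterpene = 0.30, sesquiterpene = 0.40,
                    oxidation_C7_C8 = 0.10, oxidation_C20plus = 0.10,
                    other = 0.10)
    cats <- c("A", "B", "C")
    rows <- list()
    for (ci in seq_along(cats)) {
      share <- base_share
      drop <- share["monoterpene"] * (1 - (1 - cfg$composition_effect)^(ci - 1))
      share["monoterpene"] <- share["monoterpene"] - drop
      share["oxidation_C7_C8"] <- share["oxidation_C7_C8"] + drop
      alpha <- share * cfg$dirichlet_conc
      for (s in seq_len(cfg$n_samples_per_category)) {
        g <- stats::rgamma(length(alpha), shape = alpha)
        p <- g / sum(g)
        names(p) <- names(alpha)
        total_area <- 1e6 * stats::rlnorm(1, 0, 0.2)
        sid <- sprintf("%s_%s_cat%s_s%d", cfg$zone,
                       gsub(" ", "_", cfg$species), cats[ci], s)
        cls_area <- p * total_area
        a <- cls_area[comp$class] * comp$within_class_weight
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, species = cfg$species, zone = cfg$zone,
          ozonation_category = cats[ci],
          retention_index = comp$retention_index,
          compound = comp$compound, formula = comp$formula,
          area = unname(a))
        # the residual "other" share becomes one unresolved background peak
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, species = cfg$species, zone = cfg$zone,
          ozonation_category = cats[ci], retention_index = 1900,
          compound = "unresolved background", formula = "C16H34",
          area = unname(cls_area["other"]))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
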