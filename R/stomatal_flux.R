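R_GAS <- 8.31446261815324 # J mol-1 K-1

#' Species parameter set for the multiplicative stomatal conductance model
#'
#' Builds a validated parameter set for the Jarvis-type multiplicative
#' stomatal conductance model
#' \deqn{g_{sto} = g_{max} \, f_{phen} \, f_{light} \,
#'       \max(f_{min}, f_{temp} f_{VPD} f_{SWP})}
#' with the conventional ozone-flux resistance partition on top. Defaults are
#' a boreal-conifer preset in the mapping-manual style; every constant can be
#' overridden. \code{species} selects a named preset: \code{"pinus_mugo"},
#' \code{"pinus_cembra"}, \code{"pinus_sylvestris"} (borrows the
#' \code{pinus_cembra} set), \code{"picea_abies"}, \code{"abies_alba"}
#' (borrows the \code{picea_abies} set) or \code{"boreal_conifer"}.
#'
#' @param species optional preset name (see Details); \code{NULL} uses the
#'   boreal-conifer defaults.
#' @param gmax maximum stomatal conductance to ozone, mmol O3 m-2 PLA s-1.
#' @param fmin minimum daytime fraction of \code{gmax}, in (0, 1).
#' @param light_a light-response coefficient, (umol m-2 s-1)^-1.
#' @param t_min,t_opt,t_max temperature response breakpoints, degC.
#' @param vpd_min VPD (kPa) at or below which \code{f_vpd = 1}.
#' @param vpd_max VPD (kPa) at or above which \code{f_vpd = fmin}.
#' @param fswp soil-water factor in \code{[fmin, 1]}; externally supplied
#'   scalar, default 1 (no soil-water limitation is modelled).
#' @param y_threshold POD accumulation threshold Y, nmol m-2 s-1, default 0.
#' @param leaf_dimension characteristic leaf (needle) dimension, m.
#' @param gext external (cuticular) conductance, m s-1; default 1/2500.
#' @param wind_speed default wind speed (m s-1) used for the leaf
#'   boundary-layer resistance when the series carries none.
#' @param ppfd_per_wm2 conversion from global radiation (W m-2) to PPFD
#'   (umol m-2 s-1); single documented constant, default 2.0 (PAR fraction
#'   folded in).
#' @param phen_ramp_days length (days) of the linear phenology ramps at both
#'   ends of the growing season.
#' @return object of class \code{flux_params} (named list).
#' @export
flux_params <- function(species = NULL,
                        gmax = 112, fmin = 0.1, light_a = 0.006,
                        t_min = 0, t_opt = 14, t_max = 35,
                        vpd_min = 0.5, vpd_max = 3.0,
                        fswp = 1, y_threshold = 0,
                        leaf_dimension = 0.008, gext = 1 / 2500,
                        wind_speed = 2, ppfd_per_wm2 = 2.0,
                        phen_ramp_days = 15) {
  presets <- list(
    boreal_conifer   = list(),
    pinus_mugo       = list(gmax = 118, t_opt = 16, leaf_dimension = 0.005),
    pinus_cembra     = list(gmax = 105, t_opt = 15, vpd_max = 3.2),
    picea_abies      = list(gmax = 112, t_opt = 14),
    abies_alba       = list(gmax = 112, t_opt = 14) # borrows picea_abies
  )
  presets$pinus_sylvestris <- presets$pinus_cembra   # borrows pinus_cembra
  p <- as.list(environment())
  p$species <- NULL
  if (!is.null(species)) {
    key <- tolower(gsub("[ .]", "_", species))
    if (!key %in% names(presets)) {
      stop("unknown species preset '", species, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    explicit <- names(as.list(match.call()))[-1]
    override <- presets[[key]]
    override <- override[!names(override) %in% explicit]
    p[names(override)] <- override
  }
  stopifnot(p$gmax > 0, p$fmin > 0, p$fmin < 1,
            p$t_min < p$t_opt, p$t_opt < p$t_max,
            p$vpd_min < p$vpd_max, p$light_a > 0,
            p$fswp >= p$fmin, p$fswp <= 1,
            p$leaf_dimension > 0, p$gext >= 0, p$y_threshold >= 0)
  class(p) <- "flux_params"
  p
}

#' @export
print.flux_params <- function(x, ...) {
  cat("Multiplicative stomatal conductance parameters:\n")
  cat(sprintf("  gmax = %g mmol O3 m-2 PLA s-1, fmin = %g, light_a = %g\n",
              x$gmax, x$fmin, x$light_a))
  cat(sprintf("  T(min/opt/max) = %g/%g/%g degC, VPD(min/max) = %g/%g kPa\n",
              x$t_min, x$t_opt, x$t_max, x$vpd_min, x$vpd_max))
  cat(sprintf("  fswp = %g, Y = %g nmol m-2 s-1, leaf = %g m, gext = %g m s-1\n",
              x$fswp, x$y_threshold, x$leaf_dimension, x$gext))
  invisible(x)
}

#' Temperature response of stomatal conductance
#'
#' \deqn{f_T = \frac{T - T_{min}}{T_{opt} - T_{min}}
#'   \left(\frac{T_{max} - T}{T_{max} - T_{opt}}\right)^
#'   {\frac{T_{max} - T_{opt}}{T_{opt} - T_{min}}}}
#' clipped to \code{[0, 1]}, 0 outside \code{(t_min, t_max)}.
#'
#' @param t_air air temperature, degC (vectorised).
#' @param p a [flux_params()] object.
#' @return dimensionless factor in \code{[0, 1]}.
#' @export
f_temp <- function(t_air, p) {
  ex <- (p$t_max - p$t_opt) / (p$t_opt - p$t_min)
  f <- ((t_air - p$t_min) / (p$t_opt - p$t_min)) *
    ((p$t_max - t_air) / (p$t_max - p$t_opt))^ex
  f[t_air <= p$t_min | t_air >= p$t_max] <- 0
  pmin(pmax(f, 0), 1)
}

#' Light response of stomatal conductance
#'
#' \eqn{f_{light} = 1 - e^{-a \cdot PPFD}}, in \code{[0, 1)}.
#'
#' @param ppfd photosynthetic photon flux density, umol m-2 s-1 (>= 0).
#' @param p a [flux_params()] object.
#' @return dimensionless factor.
#' @export
f_light <- function(ppfd, p) {
  if (any(ppfd < 0, na.rm = TRUE)) stop("ppfd must be >= 0")
  1 - exp(-p$light_a * ppfd)
}

#' Vapour-pressure-deficit response of stomatal conductance
#'
#' 1 at or below \code{vpd_min}, \code{fmin} at or above \code{vpd_max},
#' linear in between.
#'
#' @param vpd vapour pressure deficit, kPa.
#' @param p a [flux_params()] object.
#' @return dimensionless factor in \code{[fmin, 1]}.
#' @export
f_vpd <- function(vpd, p) {
  f <- 1 + (p$fmin - 1) * (vpd - p$vpd_min) / (p$vpd_max - p$vpd_min)
  pmin(pmax(f, p$fmin), 1)
}

#' Phenology factor
#'
#' Trapezoidal ramp over the growing season: 0 outside, linear ramps of
#' \code{phen_ramp_days} at both ends, 1 on the plateau. A zero ramp length
#' gives a rectangular window.
#'
#' @param date Date vector (or coercible).
#' @param gs a [growing_season()] object.
#' @param p a [flux_params()] object.
#' @return dimensionless factor in \code{[0, 1]}.
#' @export
f_phen <- function(date, gs, p) {
  date <- as.Date(date)
  d_from_start <- as.numeric(date - gs$start_date)
  d_to_end <- as.numeric(gs$end_date - date)
  r <- p$phen_ramp_days
  f <- rep(1, length(date))
  if (r > 0) {
    f <- pmin(1, pmin(d_from_start / r, d_to_end / r))
  }
  f[d_from_start < 0 | d_to_end < 0] <- 0
  pmax(f, 0)
}

#' Stomatal conductance (multiplicative model)
#'
#' \eqn{g_{sto} = g_{max} f_{phen} f_{light}
#'   \max(f_{min}, f_{temp} f_{VPD} f_{SWP})}, in mmol O3 m-2 PLA s-1.
#' Zero at night through \code{f_light}.
#'
#' @param t_air air temperature, degC.
#' @param ppfd photosynthetic photon flux density, umol m-2 s-1.
#' @param vpd vapour pressure deficit, kPa.
#' @param p a [flux_params()] object.
#' @param fphen phenology factor, default 1 (mid-season).
#' @return conductance in mmol O3 m-2 PLA s-1, in \code{[0, gmax]}.
#' @export
stomatal_conductance <- function(t_air, ppfd, vpd, p, fphen = 1) {
  p$gmax * fphen * f_light(ppfd, p) *
    pmax(p$fmin, f_temp(t_air, p) * f_vpd(vpd, p) * p$fswp)
}

#' Ozone concentration in nmol m-3
#'
#' Ideal-gas conversion of a mixing ratio in ppb at the measured temperature
#' and pressure: \eqn{c = ppb \cdot P / (R T)} nmol m-3.
#'
#' @param o3_ppb ozone mixing ratio, ppb.
#' @param t_air air temperature, degC.
#' @param pressure_kpa air pressure, kPa; default standard 101.325.
#' @return concentration in nmol m-3.
#' @export
o3_concentration <- function(o3_ppb, t_air, pressure_kpa = 101.325) {
  o3_ppb * 1000 * pressure_kpa / (R_GAS * (t_air + 273.15))
}

#' Hourly stomatal ozone flux
#'
#' Leaf-level ozone flux with the conventional boundary-layer / surface
#' resistance partition:
#' \deqn{F_{st} = c_{O_3} \frac{1}{r_b + r_c} \frac{r_c}{r_b + r_c}}
#' where \eqn{r_b = 1.3 \cdot 150 \sqrt{L/u}} s m-1 is the leaf
#' boundary-layer resistance, \eqn{r_c = 1/(g_{sto} + g_{ext})} the surface
#' resistance with \eqn{g_{sto}} converted from mmol m-2 s-1 to m s-1 by the
#' same ideal-gas factor, and \eqn{c_{O_3}} the concentration in nmol m-3.
#'
#' @param o3_ppb ozone mixing ratio, ppb (>= 0).
#' @param t_air air temperature, degC.
#' @param gsto stomatal conductance, mmol O3 m-2 PLA s-1.
#' @param p a [flux_params()] object.
#' @param wind_speed wind speed m s-1; defaults to \code{p$wind_speed}.
#' @param pressure_kpa air pressure, kPa.
#' @return stomatal ozone flux, nmol m-2 PLA s-1.
#' @export
stomatal_o3_flux <- function(o3_ppb, t_air, gsto, p,
                             wind_speed = NULL, pressure_kpa = 101.325) {
  if (any(o3_ppb < 0, na.rm = TRUE)) stop("o3_ppb must be >= 0")
  if (is.null(wind_speed)) wind_speed <- p$wind_speed
  if (any(wind_speed <= 0, na.rm = TRUE)) {
    stop("wind speed must be positive to compute the boundary-layer resistance")
  }
  tk <- t_air + 273.15
  gas_fac <- R_GAS * tk / (1000 * pressure_kpa)   # m3 mol-1
  gsto_ms <- gsto * 1e-3 * gas_fac                # mmol m-2 s-1 -> m s-1
  rb <- 1.3 * 150 * sqrt(p$leaf_dimension / wind_speed)
  gtot <- gsto_ms + p$gext                        # 1 / rc
  c_nmol <- o3_concentration(o3_ppb, t_air, pressure_kpa)
  # c * (1/(rb+rc)) * (rc/(rb+rc)) rewritten as c * gtot / (1 + rb*gtot)^2,
  # which stays defined for closed stomata (gtot = 0)
  c_nmol * gtot / (1 + rb * gtot)^2
}

#' Hourly flux chain over an environmental series
#'
#' Runs the multiplicative conductance model and the flux partition for every
#' hour of an environmental series. PPFD is taken from a \code{ppfd} column
#' when present, otherwise converted from \code{glob_rad_wm2} with
#' \code{p$ppfd_per_wm2}; VPD from \code{vpd_kpa}, otherwise derived from
#' \code{rh_pct} and temperature via the Magnus saturation vapour pressure.
#'
#' @param env hourly environmental series.
#' @param p a [flux_params()] object.
#' @param gs optional [growing_season()]; supplies the phenology window.
#'   Without it \code{f_phen = 1}.
#' @param o3_override optional single concentration (ppb) applied to every
#'   hour (flat profile), as used for critical-level projection.
#' @return the input data.frame with added columns \code{ppfd}, \code{vpd},
#'   \code{fphen}, \code{gsto} (mmol m-2 s-1) and \code{fst}
#'   (nmol m-2 PLA s-1).
#' @export
hourly_flux <- function(env, p, gs = NULL, o3_override = NULL) {
  env <- check_env_series(env)
  stopifnot(inherits(p, "flux_params"))
  ppfd <- if ("ppfd" %in% names(env)) env$ppfd else {
    if (!"glob_rad_wm2" %in% names(env)) {
      stop("need a ppfd or glob_rad_wm2 column")
    }
    env$glob_rad_wm2 * p$ppfd_per_wm2
  }
  vpd <- if ("vpd_kpa" %in% names(env)) env$vpd_kpa else {
    if (!"rh_pct" %in% names(env)) stop("need a vpd_kpa or rh_pct column")
    es <- 0.611 * exp(17.502 * env$t_air_c / (env$t_air_c + 240.97)) # kPa
    es * (1 - env$rh_pct / 100)
  }
  pressure <- if ("pressure_kpa" %in% names(env)) env$pressure_kpa else 101.325
  wind <- if ("wind_ms" %in% names(env)) env$wind_ms else p$wind_speed
  fphen <- if (is.null(gs)) 1 else {
    f_phen(as.Date(format(env$timestamp, "%Y-%m-%d"), tz = "UTC"), gs, p)
  }
  o3 <- if (is.null(o3_override)) env$o3_ppb else rep(o3_override, nrow(env))
  gsto <- stomatal_conductance(env$t_air_c, ppfd, vpd, p, fphen = fphen)
  fst <- stomatal_o3_flux(o3, env$t_air_c, gsto, p,
                          wind_speed = wind, pressure_kpa = pressure)
  env$ppfd <- ppfd; env$vpd <- vpd; env$fphen <- fphen
  env$gsto <- gsto; env$fst <- fst
  env
}

#' Accumulate the phytotoxic ozone dose POD_Y
#'
#' \deqn{POD_Y = \sum_{daylight\ GS\ hours} \max(0, F_{st} - Y) \cdot 3600
#'   \cdot 10^{-6}} in mmol m-2 PLA, with daylight defined as global
#' radiation >= \code{daylight_rad} W m-2.
#'
#' @param fst hourly stomatal flux, nmol m-2 PLA s-1.
#' @param glob_rad hourly global radiation, W m-2 (same length).
#' @param y flux threshold Y, nmol m-2 s-1, default 0.
#' @param daylight_rad daylight radiation threshold, W m-2, default 50.
#' @return POD_Y in mmol m-2 PLA.
#' @export
accumulate_pod <- function(fst, glob_rad, y = 0, daylight_rad = 50) {
  stopifnot(length(fst) == length(glob_rad))
  day <- !is.na(glob_rad) & glob_rad >= daylight_rad
  sum(pmax(0, fst[day] - y), na.rm = TRUE) * 3600 * 1e-6
}

#' POD_Y over a growing season
#'
#' Convenience wrapper: runs [hourly_flux()] over the growing-season subset
#' of a series and accumulates POD_Y over its daylight hours.
#'
#' @inheritParams hourly_flux
#' @param y flux threshold Y, nmol m-2 s-1; default \code{p$y_threshold}.
#' @param daylight_rad daylight radiation threshold, W m-2.
#' @return POD_Y in mmol m-2 PLA.
#' @export
compute_pod <- function(env, p, gs, y = NULL, daylight_rad = 50,
                        o3_override = NULL) {
  stopifnot(inherits(gs, "growing_season"))
  if (is.null(y)) y <- p$y_threshold
  sub <- subset_gs(check_env_series(env), gs)
  fx <- hourly_flux(sub, p, gs = gs, o3_override = o3_override)
  accumulate_pod(fx$fst, fx$glob_rad_wm2, y = y, daylight_rad = daylight_rad)
}

#' Project the flux-based critical level CL(OxS)
#'
#' Re-runs the flux chain with the ozone concentration fixed for every hour
#' to the seasonal average concentration that produces the
#' oxidative-stability threshold (flat profile), keeping the site's
#' meteorology. The resulting POD0 is the species' flux-based critical level
#' against oxidative stability.
#'
#' @param avg_o3 seasonal average hourly ozone concentration, ppb.
#' @param env hourly environmental series for the site.
#' @param p a [flux_params()] object.
#' @param gs a [growing_season()] object.
#' @param y flux threshold, default 0 (POD0).
#' @return CL(OxS) as POD0 in mmol m-2 PLA.
#' @export
project_cl_oxs <- function(avg_o3, env, p, gs, y = 0) {
  if (avg_o3 < 0) stop("avg_o3 must be >= 0")
  compute_pod(env, p, gs, y = y, o3_override = avg_o3)
}

#' Ozone tolerance-potential utilisation
#'
#' \code{100 * pod_ambient / pod_cl}: the share of a species' ozone-tolerance
#' potential consumed under ambient conditions. Report to one decimal.
#'
#' @param pod_ambient POD0 under ambient ozone, mmol m-2.
#' @param pod_cl CL(OxS) as POD0, mmol m-2; must be > 0.
#' @return utilisation in percent.
#' @examples
#' round(tolerance_utilisation(8.2, 32.2), 1) # 25.5
#' @export
tolerance_utilisation <- function(pod_ambient, pod_cl) {
  if (any(pod_cl <= 0)) stop("pod_cl must be > 0")
  100 * pod_ambient / pod_cl
}
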