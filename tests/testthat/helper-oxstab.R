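# Build a full-year hourly environmental series with constant fields.
# cold_months: months that get one all-cold day (hourly temps forced to 0)
# on the 15th, so the 5 degC growing-season rule disqualifies them.
make_env <- function(year = 2023, t_air = 10, o3 = 50, rad = NULL,
                     cold_months = integer(0), warm_months = integer(0),
                     warm_boost = 5) {
  ts <- seq(as.POSIXct(paste0(year, "-01-01 00:00:00"), tz = "UTC"),
            as.POSIXct(paste0(year, "-12-31 23:00:00"), tz = "UTC"),
            by = "1 hour")
  n <- length(ts)
  hr <- as.integer(format(ts, "%H"))
  mon <- as.integer(format(ts, "%m"))
  mday <- as.integer(format(ts, "%d"))
  t <- rep(t_air, n)
  t[mon %in% warm_months] <- t_air + warm_boost
  t[mon %in% cold_months & mday == 15L] <- 0
  if (is.null(rad)) rad <- ifelse(hr >= 7 & hr <= 17, 500, 0)
  data.frame(timestamp = ts, t_air_c = t,
             o3_ppb = rep_len(o3, n), glob_rad_wm2 = rep_len(rad, n),
             vpd_kpa = 0.8)
}

# Frozen oracle values (computed independently before the implementation,
# by direct normal equations / grid scan / single-expression evaluation).
oracle <- list(
  # degree-2 normal-equations fit of the foothill P. mugo OxS series
  fh_mugo_quad = c(4.66487584391e-03, -9.90086353765e-05, -7.6382101946e-08),
  # first -0.05 crossing of the degree-2 fit to the treeline P. mugo series,
  # dense grid scan at 0.01 ppm
  ate_mugo_root = 491.89,
  fh_mugo_root = 417.60,
  # single-expression resistance-chain evaluation:
  # T=18 degC, PPFD=800, VPD=1.2 kPa, O3=50 ppb, P=101.325 kPa, u=2 m/s,
  # L=0.008 m, gext=1/2500, boreal-conifer defaults
  flux_record = list(gsto = 77.8071679286, fst = 4.47470254879),
  # hand sums-of-squares decomposition for a fixed 3 x 4 table
  anova_F = 134.671378092,
  anova_p = 1.96553887279e-07
)
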