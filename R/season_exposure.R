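#' Growing-season object
#'
#' A growing season is represented at month granularity: it spans the first
#' day of its first month to the last day of its last month, and its hour
#' count is 24 x the calendar day count.
#'
#' @param start_date,end_date Date (or ISO "YYYY-MM-DD" strings), inclusive.
#' @return object of class \code{growing_season}: list with \code{start_date},
#'   \code{end_date}, \code{days} and \code{hours}.
#' @examples
#' growing_season("2023-06-01", "2023-09-30")$hours # 2928
#' @export
growing_season <- function(start_date, end_date) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) stop("invalid date(s)")
  if (start_date > end_date) stop("start_date must not be after end_date")
  days <- as.integer(end_date - start_date) + 1L
  out <- list(start_date = start_date, end_date = end_date,
              days = days, hours = 24L * days)
  class(out) <- "growing_season"
  out
}

#' @export
print.growing_season <- function(x, ...) {
  cat(sprintf("Growing season %s to %s (%d days, %d hours)\n",
              format(x$start_date), format(x$end_date), x$days, x$hours))
  invisible(x)
}

gs_hours <- function(gs) {
  if (inherits(gs, "growing_season")) gs$hours else as.numeric(gs)
}

check_env_series <- function(env) {
  req <- c("timestamp", "t_air_c", "o3_ppb")
  miss <- setdiff(req, names(env))
  if (length(miss)) {
    stop("environmental series is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!inherits(env$timestamp, "POSIXct")) {
    env$timestamp <- as.POSIXct(env$timestamp, tz = "UTC")
  }
  dt <- diff(as.numeric(env$timestamp))
  if (any(dt != 3600)) {
    stop("timestamps must be strictly increasing at exact 1 h steps")
  }
  if (any(env$o3_ppb < 0, na.rm = TRUE)) stop("o3_ppb must be >= 0")
  if ("rh_pct" %in% names(env) &&
      any(env$rh_pct < 0 | env$rh_pct > 100, na.rm = TRUE)) {
    stop("rh_pct must lie in [0, 100]")
  }
  env
}

#' Read an hourly environmental series from CSV
#'
#' Expects columns \code{timestamp} (hourly, left-labelled, local standard
#' time, ISO 8601), \code{t_air_c}, \code{o3_ppb} and optionally
#' \code{glob_rad_wm2}, \code{vpd_kpa}, \code{rh_pct}, \code{pressure_kpa}.
#'
#' @param path path to the CSV file.
#' @return validated data.frame with a POSIXct \code{timestamp} column.
#' @export
read_env_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"timestamp" %in% names(df)) {
    stop("schema error in ", path, ": missing 'timestamp' column")
  }
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S",
                                            "%Y-%m-%d %H:%M"))
  check_env_series(df)
}

#' Detect the growing season from hourly air temperature
#'
#' A calendar month qualifies as part of the growing season if it contains no
#' day whose 24 hourly air temperatures are all below the threshold (default
#' 5 degC). The season is the longest contiguous run of qualifying months;
#' ties are broken toward the run containing the warmest month (by mean
#' hourly temperature). The series must cover whole calendar months.
#'
#' @param env hourly environmental series (data.frame as from
#'   [read_env_csv()] or [generate_env_series()]).
#' @param threshold temperature threshold in degC, default 5.
#' @return a [growing_season()] object.
#' @export
detect_growing_season <- function(env, threshold = 5) {
  env <- check_env_series(env)
  ts <- env$timestamp
  day <- as.Date(format(ts, "%Y-%m-%d"), tz = "UTC")
  month <- format(day, "%Y-%m")
  # whole-month coverage: each covered month must have 24 * <days in month> rows
  hrs_by_month <- table(month)
  for (m in names(hrs_by_month)) {
    first <- as.Date(paste0(m, "-01"))
    dim_m <- as.integer(seq(first, by = "1 month", length.out = 2)[2] - first)
    if (hrs_by_month[[m]] != 24L * dim_m) {
      stop("coverage error: month ", m, " is incomplete (",
           hrs_by_month[[m]], " of ", 24L * dim_m, " hours)")
    }
  }
  if (anyNA(env$t_air_c)) stop("coverage error: missing air temperatures")
  all_cold_day <- tapply(env$t_air_c, day, function(x) all(x < threshold))
  month_of_day <- format(as.Date(names(all_cold_day)), "%Y-%m")
  qualifies <- !tapply(all_cold_day, month_of_day, any)
  months <- names(qualifies)
  if (!any(qualifies)) stop("no month qualifies under the ", threshold,
                            " degC rule")
  # longest contiguous run of qualifying months
  r <- rle(as.vector(qualifies))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best_len <- max(r$lengths[cand])
  cand <- cand[r$lengths[cand] == best_len]
  if (length(cand) > 1) {
    mean_t <- tapply(env$t_air_c, month, mean)
    warmest <- names(mean_t)[which.max(mean_t)]
    wi <- match(warmest, months)
    containing <- cand[starts[cand] <= wi & ends[cand] >= wi]
    cand <- if (length(containing)) containing[1] else cand[1]
  }
  first_m <- months[starts[cand[1]]]
  last_m <- months[ends[cand[1]]]
  start_date <- as.Date(paste0(first_m, "-01"))
  last_first <- as.Date(paste0(last_m, "-01"))
  end_date <- seq(last_first, by = "1 month", length.out = 2)[2] - 1
  growing_season(start_date, end_date)
}

subset_gs <- function(env, gs) {
  day <- as.Date(format(env$timestamp, "%Y-%m-%d"), tz = "UTC")
  env[day >= gs$start_date & day <= gs$end_date, , drop = FALSE]
}

#' Cumulative ozone exposure (sumO3) over a growing season
#'
#' Sums hourly ozone concentrations (ppb) over the growing season and divides
#' by 1000 to give sumO3 in ppm. Missing hours are excluded with a message;
#' if valid coverage falls below \code{min_coverage} of the season's hours an
#' error is raised rather than silently extrapolating.
#'
#' @param env hourly environmental series.
#' @param gs a [growing_season()] object.
#' @param min_coverage minimum fraction of season hours with valid ozone,
#'   default 0.9.
#' @param round_to optional rounding unit in ppm (e.g. 10 to round to the
#'   nearest ten ppm); default \code{NULL}, no rounding.
#' @return sumO3 in ppm.
#' @export
cumulative_exposure <- function(env, gs, min_coverage = 0.9, round_to = NULL) {
  env <- check_env_series(env)
  stopifnot(inherits(gs, "growing_season"))
  sub <- subset_gs(env, gs)
  o3 <- sub$o3_ppb
  n_valid <- sum(!is.na(o3))
  if (n_valid < min_coverage * gs$hours) {
    stop("data-coverage error: only ", n_valid, " of ", gs$hours,
         " growing-season hours have valid ozone (need >= ",
         round(100 * min_coverage), " %)")
  }
  if (anyNA(o3)) {
    message("excluding ", sum(is.na(o3)), " missing ozone hour(s)")
  }
  s <- sum(o3, na.rm = TRUE) / 1000
  if (!is.null(round_to)) s <- round_to * round(s / round_to)
  s
}

#' Convert seasonal sumO3 to the average hourly concentration
#'
#' \code{avg_o3 = 1000 * sum_o3 / hours}; the exact inverse of
#' [avg_to_sum()]. Report to one decimal.
#'
#' @param sum_o3 cumulative exposure, ppm.
#' @param gs a [growing_season()] object or an hour count.
#' @return average hourly ozone concentration, ppb.
#' @examples
#' sum_to_avg(464.0, growing_season("2023-06-01", "2023-09-30")) # 158.47
#' @export
sum_to_avg <- function(sum_o3, gs) {
  h <- gs_hours(gs)
  if (h <= 0) stop("growing season must have positive hours")
  1000 * sum_o3 / h
}

#' Convert an average hourly concentration to seasonal sumO3
#'
#' @param avg_o3 average hourly ozone concentration, ppb.
#' @param gs a [growing_season()] object or an hour count.
#' @return cumulative exposure, ppm.
#' @export
avg_to_sum <- function(avg_o3, gs) {
  h <- gs_hours(gs)
  if (h <= 0) stop("growing season must have positive hours")
  avg_o3 * h / 1000
}

#' AOT40 exposure metric
#'
#' Accumulated ozone exposure over a 40 ppb threshold during daylight hours
#' of the growing season: \eqn{\sum \max(0, O_3 - 40)/1000} ppm h, with
#' daylight defined as global radiation >= \code{daylight_rad} W m-2.
#'
#' @param env hourly environmental series with a \code{glob_rad_wm2} column.
#' @param gs a [growing_season()] object.
#' @param daylight_rad daylight radiation threshold, W m-2, default 50.
#' @param threshold_ppb concentration cut-off, default 40 ppb.
#' @return AOT40 in ppm h.
#' @export
aot40 <- function(env, gs, daylight_rad = 50, threshold_ppb = 40) {
  env <- check_env_series(env)
  stopifnot(inherits(gs, "growing_season"))
  if (!"glob_rad_wm2" %in% names(env)) {
    stop("AOT40 needs a glob_rad_wm2 column to define daylight hours")
  }
  sub <- subset_gs(env, gs)
  day <- !is.na(sub$glob_rad_wm2) & sub$glob_rad_wm2 >= daylight_rad
  sum(pmax(0, sub$o3_ppb[day] - threshold_ppb), na.rm = TRUE) / 1000
}
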