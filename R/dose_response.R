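#' Exponential zero-ozone baseline fit
#'
#' Fits the injury-exposure relationship \eqn{INX = a e^{b\,sumO_3}} by
#' ordinary least squares on the log scale (\code{lm(log(inx) ~ sum_o3)}).
#' The intercept back-transform \eqn{a = e^{\hat\alpha}} is the modelled
#' zero-ozone injury baseline \code{INX(0)}, used as the reference level in
#' oxidative-stability calculations in place of unavailable unexposed control
#' samples.
#'
#' @param sum_o3 cumulative ozone exposure, ppm (ppb h / 1000); strictly
#'   increasing, all positive.
#' @param inx injury indices in percent, all > 0 (the log transform must be
#'   defined).
#' @return an object of class \code{exp_baseline}: list with \code{a}
#'   (percent, = INX(0)), \code{b} (per ppm), \code{r} (signed correlation of
#'   the log-linear fit), \code{p} (marginal significance of the slope),
#'   \code{fitted}, \code{residuals} (log scale) and \code{data}.
#' @examples
#' fit <- fit_exponential_baseline(c(154, 323, 668, 991, 1312, 1825),
#'                                 c(12.7, 14.3, 17.1, 23.7, 34.9, 43.2))
#' round(fit$a, 1)
#' @export
fit_exponential_baseline <- function(sum_o3, inx) {
  sum_o3 <- as.numeric(sum_o3); inx <- as.numeric(inx)
  if (length(sum_o3) != length(inx)) stop("sum_o3 and inx differ in length")
  if (length(inx) < 3) stop("insufficient data: need at least 3 points")
  if (any(!is.finite(sum_o3)) || any(!is.finite(inx))) stop("non-finite input")
  if (any(inx <= 0)) stop("all inx must be > 0 for the log-linear fit")
  if (any(sum_o3 <= 0)) stop("all sum_o3 must be > 0")
  if (is.unsorted(sum_o3, strictly = TRUE)) {
    stop("sum_o3 must be strictly increasing")
  }
  fit <- stats::lm(log(inx) ~ sum_o3)
  co <- stats::coef(fit)
  sm <- summary(fit)
  out <- list(
    a = unname(exp(co[1])),
    b = unname(co[2]),
    r = unname(sign(co[2]) * sqrt(sm$r.squared)),
    p = unname(sm$coefficients[2, 4]),
    fitted = unname(exp(stats::fitted(fit))),
    residuals = unname(stats::residuals(fit)),
    data = data.frame(sum_o3 = sum_o3, inx = inx)
  )
  class(out) <- "exp_baseline"
  out
}

#' @export
print.exp_baseline <- function(x, ...) {
  cat("Exponential baseline fit: INX = a * exp(b * sumO3)\n")
  cat(sprintf("  INX(0) = a = %.1f %%   b = %.3e per ppm\n", x$a, x$b))
  cat(sprintf("  r = %.3f, p = %.3g (log-linear OLS, n = %d)\n",
              x$r, x$p, nrow(x$data)))
  invisible(x)
}

#' Oxidative stability
#'
#' The oxidative-stability statistic of an ozonation series member:
#' \deqn{OxS(n) = -\frac{INX(n) - INX(0)}{100}}
#' i.e. the injury increase over the zero-ozone baseline converted from a
#' percentage to a decimal, with sign flipped so that values run from 0
#' (oxidatively stable) down to -1 (complete membrane destruction above
#' baseline). Positive raw values (injury below baseline) are clipped to 0
#' with a warning.
#'
#' @param inx_n injury index of series member n, percent in \code{[0, 100]}.
#' @param inx_0 baseline injury index \code{INX(0)}, percent in
#'   \code{[0, 100]}. Recycled against \code{inx_n}.
#' @return numeric vector of OxS values in \code{[-1, 0]} (full precision;
#'   round to 2 decimals for reporting).
#' @examples
#' round(compute_oxs(48.4, 9.3), 2) # -0.39
#' @export
compute_oxs <- function(inx_n, inx_0) {
  inx_n <- as.numeric(inx_n); inx_0 <- as.numeric(inx_0)
  n <- max(length(inx_n), length(inx_0))
  inx_n <- rep_len(inx_n, n); inx_0 <- rep_len(inx_0, n)
  if (any(!is.finite(inx_n)) || any(!is.finite(inx_0))) stop("non-finite input")
  if (any(inx_n < 0 | inx_n > 100) || any(inx_0 < 0 | inx_0 > 100)) {
    stop("injury indices must lie in [0, 100]")
  }
  oxs <- -(inx_n - inx_0) / 100
  if (any(oxs > 0)) {
    warning("clipping ", sum(oxs > 0),
            " positive OxS value(s) (injury below baseline) to 0")
    oxs[oxs > 0] <- 0
  }
  oxs
}

#' Polynomial dose-response fit of OxS against cumulative ozone
#'
#' Least-squares polynomial (default degree 2) describing oxidative stability
#' as a function of cumulative ozone exposure, with a pointwise 0.95
#' confidence band over the observed dose range.
#'
#' @param sum_o3 cumulative ozone exposure, ppm.
#' @param oxs oxidative-stability values in \code{[-1, 0]}.
#' @param degree polynomial degree (default 2); must be < number of points.
#' @param conf_points number of evaluation points for the confidence band.
#' @return an object of class \code{oxs_polyfit}: list with
#'   \code{coefficients} (ascending powers), \code{degree}, \code{domain},
#'   \code{r_squared}, \code{residuals}, \code{conf_band} (data.frame
#'   \code{sum_o3}, \code{fit}, \code{lwr}, \code{upr}), \code{data} and the
#'   underlying \code{lm} object.
#' @export
fit_dose_response <- function(sum_o3, oxs, degree = 2, conf_points = 101) {
  sum_o3 <- as.numeric(sum_o3); oxs <- as.numeric(oxs)
  if (length(sum_o3) != length(oxs)) stop("sum_o3 and oxs differ in length")
  if (degree < 1) stop("degree must be >= 1")
  if (length(sum_o3) <= degree) {
    stop("rank error: need more points (", length(sum_o3),
         ") than the polynomial degree (", degree, ")")
  }
  df <- data.frame(sum_o3 = sum_o3, oxs = oxs)
  fit <- stats::lm(oxs ~ poly(sum_o3, degree, raw = TRUE), data = df)
  grid <- data.frame(sum_o3 = seq(min(sum_o3), max(sum_o3),
                                  length.out = conf_points))
  band <- stats::predict(fit, grid, interval = "confidence", level = 0.95)
  out <- list(
    coefficients = unname(stats::coef(fit)),
    degree = degree,
    domain = c(0, max(sum_o3)),
    r_squared = summary(fit)$r.squared,
    residuals = unname(stats::residuals(fit)),
    conf_band = data.frame(sum_o3 = grid$sum_o3, fit = band[, "fit"],
                           lwr = band[, "lwr"], upr = band[, "upr"]),
    data = df,
    lm = fit
  )
  class(out) <- "oxs_polyfit"
  out
}

#' Evaluate a fitted dose-response polynomial
#'
#' @param object an \code{oxs_polyfit}.
#' @param newdata numeric vector of doses (ppm) at which to evaluate; if a
#'   data.frame, its \code{sum_o3} column is used.
#' @param ... unused.
#' @return fitted OxS values.
#' @export
predict.oxs_polyfit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$sum_o3 else as.numeric(newdata)
  co <- object$coefficients
  vapply(x, function(z) sum(co * z^(seq_along(co) - 1)), numeric(1))
}

#' @export
print.oxs_polyfit <- function(x, ...) {
  cat(sprintf("Polynomial dose-response fit (degree %d), R^2 = %.3f\n",
              x$degree, x$r_squared))
  cat("  coefficients (ascending powers):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Invert a dose-response fit at the oxidative-stability threshold
#'
#' Finds the smallest positive cumulative ozone dose at which the fitted
#' polynomial reaches the oxidative-stability threshold (default -0.05, the
#' 5 % injury level). The curve is scanned over \code{[0, search_max]} for
#' the first sign change and the crossing refined by bisection to
#' \code{|f(x) - threshold| <= 1e-9}.
#'
#' @param fit an \code{oxs_polyfit}.
#' @param threshold OxS threshold, in (-1, 0). Default -0.05.
#' @param search_max upper end of the root search; default twice the largest
#'   observed dose.
#' @return list of class \code{critical_dose}: \code{sum_o3_oxs} (ppm),
#'   \code{threshold} and \code{extrapolated} (TRUE when the crossing lies
#'   beyond the largest observed dose).
#' @examples
#' f <- fit_dose_response(c(100, 500, 1000), c(-0.01, -0.05, -0.10), degree = 1)
#' invert_threshold(f)$sum_o3_oxs
#' @export
invert_threshold <- function(fit, threshold = -0.05, search_max = NULL) {
  stopifnot(inherits(fit, "oxs_polyfit"))
  if (!(threshold > -1 && threshold < 0)) {
    stop("threshold must lie in (-1, 0)")
  }
  max_obs <- max(fit$data$sum_o3)
  if (is.null(search_max)) search_max <- 2 * max_obs
  f <- function(x) predict(fit, x) - threshold
  # locate the first sign change on a fine grid
  grid <- seq(0, search_max, length.out = 4096)
  fg <- f(grid)
  sgn <- sign(fg)
  idx <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                 (sgn[-1] != 0 | sgn[-length(sgn)] != 0))
  exact <- which(fg == 0 & grid > 0)
  if (!length(idx) && !length(exact)) {
    stop("no crossing of the threshold ", threshold, " in [0, ",
         signif(search_max, 6), "]")
  }
  if (length(exact) && (!length(idx) || grid[exact[1]] <= grid[idx[1]])) {
    root <- grid[exact[1]]
  } else {
    i <- idx[1]
    root <- stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                           tol = 1e-12)$root
    # polish by bisection to the stated tolerance on |f|
    lo <- grid[i]; up <- grid[i + 1]
    while (abs(f(root)) > 1e-9 && up - lo > .Machine$double.eps * up) {
      if (sign(f(lo)) * sign(f(root)) <= 0) up <- root else lo <- root
      root <- (lo + up) / 2
    }
  }
  if (root <= 0) stop("no positive crossing of the threshold found")
  out <- list(sum_o3_oxs = root, threshold = threshold,
              extrapolated = root > max_obs)
  class(out) <- "critical_dose"
  out
}

#' @export
print.critical_dose <- function(x, ...) {
  cat(sprintf("sumO3(OxS) = %.1f ppm at OxS threshold %.2f%s\n",
              x$sum_o3_oxs, x$threshold,
              if (x$extrapolated) " (extrapolated beyond observed doses)" else ""))
  invisible(x)
}
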