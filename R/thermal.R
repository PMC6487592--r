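#' Cardinal-temperature response for leaf initiation and growth
#'
#' Builds the beta-shaped temperature response used throughout the package.
#' The shape exponent is derived from the three cardinal temperatures as
#' `alpha = ln(2) / ln((t_max - t_min) / (t_opt - t_min))`, which guarantees
#' that the response equals 1 at `t_opt` and 0 at both `t_min` and `t_max`.
#'
#' Defaults (0, 27.5, 40 degC) are the cardinal temperatures commonly used
#' for wheat leaf initiation and extension.
#'
#' @param t_min,t_opt,t_max Cardinal temperatures (degC), `t_min < t_opt < t_max`.
#' @return An object of class `temperature_response` with fields `t_min`,
#'   `t_opt`, `t_max` and the derived exponent `alpha`.
#' @examples
#' resp <- temperature_response()
#' beta_response(c(0, 20, 27.5, 40), resp)
#' @export
temperature_response <- function(t_min = 0, t_opt = 27.5, t_max = 40) {
  stopifnot(is.numeric(t_min), is.numeric(t_opt), is.numeric(t_max),
            length(t_min) == 1, length(t_opt) == 1, length(t_max) == 1)
  if (!(t_min < t_opt && t_opt < t_max)) {
    abort("cardinal temperatures must satisfy t_min < t_opt < t_max",
          class = "larwheat_bad_cardinals")
  }
  alpha <- log(2) / log((t_max - t_min) / (t_opt - t_min))
  structure(list(t_min = t_min, t_opt = t_opt, t_max = t_max, alpha = alpha),
            class = "temperature_response")
}

#' @export
print.temperature_response <- function(x, ...) {
  cat(sprintf(
    "<temperature_response> t_min = %g, t_opt = %g, t_max = %g degC (alpha = %.4f)\n",
    x$t_min, x$t_opt, x$t_max, x$alpha))
  invisible(x)
}

#' Beta temperature-response function
#'
#' Dimensionless development-rate multiplier
#' `f(T) = max(0, 2 x^alpha - x^(2 alpha))` with
#' `x = (T - t_min) / (t_opt - t_min)`, clamped to 0 outside
#' `(t_min, t_max)`. Equals 1 at `t_opt`.
#'
#' @param temp Temperature(s), degC. Must be finite.
#' @param resp A [temperature_response()].
#' @return Numeric vector in `[0, 1]`.
#' @export
beta_response <- function(temp, resp = temperature_response()) {
  stopifnot(inherits(resp, "temperature_response"))
  if (!is.numeric(temp) || any(!is.finite(temp))) {
    abort("`temp` must be finite numeric", class = "larwheat_bad_temperature")
  }
  x <- (temp - resp$t_min) / (resp$t_opt - resp$t_min)
  xa <- ifelse(x > 0, x^resp$alpha, 0)
  f <- pmax(0, 2 * xa - xa^2)
  f[temp <= resp$t_min | temp >= resp$t_max] <- 0
  f
}

#' Daily thermal time from a sub-daily temperature series
#'
#' Thermal time accumulated over one day, computed as
#' `t_opt * mean(f(T_i))` over a uniform sub-daily temperature series
#' (the reference discretisation is 144 ten-minute means of apex
#' temperature). Bounded by `[0, t_opt]` degree-days.
#'
#' @param subdaily_temp Numeric vector of temperatures (degC) covering exactly
#'   one day at a uniform time step.
#' @param resp A [temperature_response()].
#' @return Daily thermal time, degC d (degree-days).
#' @export
daily_thermal_time <- function(subdaily_temp, resp = temperature_response()) {
  if (length(subdaily_temp) == 0) {
    abort("empty sub-daily temperature series", class = "larwheat_empty_series")
  }
  resp$t_opt * mean(beta_response(subdaily_temp, resp))
}

#' Photothermal quotient
#'
#' Ratio of daily photosynthetically active radiation to daily thermal time
#' (mol m-2 degCd-1): the potential carbon supply per unit of developmental
#' demand. Undefined when no thermal time accrues (development is stalled),
#' which is an error rather than an infinity.
#'
#' @param daily_par Daily PAR, mol m-2 d-1 (>= 0).
#' @param daily_tt Daily thermal time, degC d (> 0).
#' @return PTQ, mol m-2 degCd-1.
#' @export
photothermal_quotient <- function(daily_par, daily_tt) {
  stopifnot(is.numeric(daily_par), is.numeric(daily_tt))
  if (any(daily_par < 0, na.rm = TRUE)) {
    abort("daily PAR must be >= 0", class = "larwheat_negative_par")
  }
  if (any(daily_tt <= 0, na.rm = TRUE)) {
    abort("PTQ undefined: daily thermal time must be > 0",
          class = "larwheat_zero_thermal_time")
  }
  daily_par / daily_tt
}

#' Convert an instantaneous PAR flux to a daily PAR sum
#'
#' `flux (umol m-2 s-1) * photoperiod (h) * 3600 (s h-1) * 1e-6 (mol umol-1)`.
#' Used to turn growth-chamber set points into daily totals.
#'
#' @param par_flux PAR flux, umol m-2 s-1.
#' @param photoperiod Hours of light per day.
#' @return Daily PAR, mol m-2 d-1.
#' @export
par_flux_to_daily <- function(par_flux, photoperiod) {
  stopifnot(all(par_flux >= 0), all(photoperiod >= 0), all(photoperiod <= 24))
  par_flux * photoperiod * 3600 * 1e-6
}

#' Astronomical daylength
#'
#' Daylength (h) from standard solar-declination geometry
#' (via [geosphere::daylength()]). Restricted to latitudes within the
#' polar circles, where sunrise and sunset occur every day of the year.
#'
#' @param latitude Degrees, positive north; `|latitude| <= 66`.
#' @param doy Day of year (1-366).
#' @return Daylength in hours.
#' @export
day_length <- function(latitude, doy) {
  if (any(abs(latitude) > 66)) {
    abort("|latitude| must be <= 66 (polar day/night not supported)",
          class = "larwheat_polar_latitude")
  }
  stopifnot(all(doy >= 1), all(doy <= 366))
  geosphere::daylength(latitude, doy)
}

#' Sine-based diurnal temperature course
#'
#' Expands a daily minimum/maximum pair into a smooth within-day course,
#' `T(h) = (tmax + tmin)/2 - (tmax - tmin)/2 * cos(2 pi (h - 3) / 24)`,
#' i.e. a sinusoid with its minimum at 03:00 and maximum at 15:00. This is
#' the default interpolation used when only daily weather is available;
#' chamber scenarios use their exact square-wave set points instead.
#'
#' @param tmin,tmax Daily extreme temperatures, degC.
#' @param hours Hours of day at which to evaluate (default: 144 ten-minute
#'   interval midpoints).
#' @return Numeric vector of temperatures at `hours`.
#' @export
diurnal_temperature <- function(tmin, tmax, hours = subdaily_hours()) {
  stopifnot(length(tmin) == 1, length(tmax) == 1, tmax >= tmin)
  mid <- (tmax + tmin) / 2
  amp <- (tmax - tmin) / 2
  mid - amp * cos(2 * pi * (hours - 3) / 24)
}

#' Midpoints of the reference sub-daily discretisation
#'
#' @param n_steps Number of uniform steps per day (default 144, i.e. 10 min).
#' @return Hour-of-day midpoints, length `n_steps`.
#' @export
subdaily_hours <- function(n_steps = 144) {
  stopifnot(n_steps >= 1)
  (seq_len(n_steps) - 0.5) * 24 / n_steps
}
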