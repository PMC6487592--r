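#' Weather series containers
#'
#' Two tabular weather containers are used throughout the package, both plain
#' tibbles with a class tag and validated invariants:
#'
#' * `subdaily_weather`: one row per sub-daily step, columns `day` (integer,
#'   1-based), `hour` (hour-of-day midpoint), `tair_c` (air temperature, degC),
#'   optionally `tapex_c` (apex/organ temperature; defaults to air) and
#'   `par_umol` (PAR flux, umol m-2 s-1). The step must divide 24 h evenly
#'   and be identical on every day.
#' * `daily_weather`: one row per day, columns `date` (Date), `doy`,
#'   `tmin_c`, `tmax_c`, `par_mol_m2` (daily PAR, mol m-2 d-1), with the site
#'   latitude stored as an attribute. Sub-daily temperatures are derived on
#'   demand with [diurnal_temperature()].
#'
#' @name weather-series
NULL

#' Construct a sub-daily weather series
#'
#' @param day Integer day index (1-based), strictly grouped and complete.
#' @param hour Hour-of-day midpoints, identical within every day and dividing
#'   24 h evenly.
#' @param tair_c Air temperature, degC.
#' @param par_umol PAR flux, umol m-2 s-1 (>= 0).
#' @param tapex_c Optional apex temperature, degC; defaults to `tair_c`.
#' @return A `subdaily_weather` tibble.
#' @export
subdaily_weather <- function(day, hour, tair_c, par_umol, tapex_c = NULL) {
  x <- tibble(day = as.integer(day), hour = hour, tair_c = tair_c,
              tapex_c = if (is.null(tapex_c)) tair_c else tapex_c,
              par_umol = par_umol)
  validate_subdaily(x)
}

validate_subdaily <- function(x) {
  steps <- x$hour[x$day == x$day[1]]
  n <- length(steps)
  if (n < 1) abort("empty weather series", class = "larwheat_empty_series")
  if (n > 1) {
    dh <- diff(steps)
    if (any(dh <= 0)) {
      abort("time must be strictly increasing within a day",
            class = "larwheat_nonmonotone_time")
    }
    if (max(abs(dh - 24 / n)) > 1e-9) {
      abort("sub-daily step must be uniform and divide 24 h evenly",
            class = "larwheat_bad_step")
    }
  }
  if (!all(table(x$day) == n)) {
    abort("every day must have the same number of sub-daily steps",
          class = "larwheat_bad_step")
  }
  if (any(x$par_umol < 0)) {
    abort("PAR must be >= 0", class = "larwheat_negative_par")
  }
  class(x) <- c("subdaily_weather", class(tibble()))
  x
}

#' Construct a daily weather series
#'
#' @param date `Date` vector, strictly increasing, no gaps.
#' @param tmin_c,tmax_c Daily extreme air temperatures, degC.
#' @param par_mol_m2 Daily PAR, mol m-2 d-1 (>= 0).
#' @param latitude Site latitude, degrees (positive north).
#' @return A `daily_weather` tibble with a `latitude` attribute and a `doy`
#'   column.
#' @export
daily_weather <- function(date, tmin_c, tmax_c, par_mol_m2, latitude = 45) {
  date <- as.Date(date)
  d <- as.numeric(diff(date))
  if (length(d) && any(d <= 0)) {
    abort("dates must be strictly increasing", class = "larwheat_nonmonotone_time")
  }
  if (length(d) && any(d != 1)) {
    gap <- date[which(d != 1)[1]]
    abort(sprintf("date gap after %s", format(gap)), class = "larwheat_date_gap")
  }
  if (any(par_mol_m2 < 0)) {
    abort("PAR must be >= 0", class = "larwheat_negative_par")
  }
  if (any(tmax_c < tmin_c)) {
    abort("tmax_c must be >= tmin_c", class = "larwheat_bad_temperature")
  }
  x <- tibble(date = date, doy = as.integer(strftime(date, "%j")),
              tmin_c = tmin_c, tmax_c = tmax_c, par_mol_m2 = par_mol_m2)
  attr(x, "latitude") <- latitude
  class(x) <- c("daily_weather", class(tibble()))
  x
}

#' Daily developmental forcing from a weather series
#'
#' Reduces a weather series to the per-day quantities the LAR models consume:
#' daily thermal time (degC d), daily PAR (mol m-2 d-1) and their ratio, the
#' photothermal quotient. Sub-daily series are integrated directly over their
#' own steps; daily series are first expanded to the 144-step reference
#' discretisation with [diurnal_temperature()].
#'
#' @param weather A `subdaily_weather` or `daily_weather` object.
#' @param resp A [temperature_response()].
#' @param temperature Which temperature column to integrate for sub-daily
#'   series: `"apex"` (default) or `"air"`.
#' @return A tibble with one row per day: `day`, `date` (daily series only),
#'   `tt_cd`, `par_mol_m2`, `ptq` (NA when `tt_cd == 0`).
#' @export
daily_forcing <- function(weather, resp = temperature_response(),
                          temperature = c("apex", "air")) {
  temperature <- match.arg(temperature)
  if (inherits(weather, "subdaily_weather")) {
    temp_col <- if (temperature == "apex") weather$tapex_c else weather$tair_c
    days <- sort(unique(weather$day))
    step_h <- 24 / sum(weather$day == weather$day[1])
    tt <- vapply(days, function(d) {
      daily_thermal_time(temp_col[weather$day == d], resp)
    }, numeric(1))
    par <- vapply(days, function(d) {
      sum(weather$par_umol[weather$day == d]) * step_h * 3600 * 1e-6
    }, numeric(1))
    out <- tibble(day = days, tt_cd = tt, par_mol_m2 = par)
  } else if (inherits(weather, "daily_weather")) {
    hrs <- subdaily_hours()
    tt <- mapply(function(lo, hi) {
      daily_thermal_time(diurnal_temperature(lo, hi, hrs), resp)
    }, weather$tmin_c, weather$tmax_c)
    out <- tibble(day = seq_len(nrow(weather)), date = weather$date,
                  tt_cd = as.numeric(tt), par_mol_m2 = weather$par_mol_m2)
  } else {
    abort("`weather` must be a subdaily_weather or daily_weather object",
          class = "larwheat_bad_weather")
  }
  out$ptq <- ifelse(out$tt_cd > 0, out$par_mol_m2 / out$tt_cd, NA_real_)
  out
}
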