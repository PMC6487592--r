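#' Growth-chamber treatment reference table
#'
#' The growth-chamber treatments used to calibrate the LAR-PTQ response:
#' set-point day/night air temperature, PAR flux and photoperiod, plus the
#' measured mean daily PAR (mol m-2 d-1), mean daily thermal time (degC d),
#' photothermal quotient (mol m-2 degCd-1) and initial leaf appearance rate
#' (x 1e-3 leaves degCd-1, mean and SD) for each treatment. Measured columns
#' are observed chamber means, not set-point arithmetic, so they differ
#' slightly from values recomputed from the set points.
#'
#' Swap treatments (`280-170`, `170-280`) changed the PAR flux when plants
#' had 3.5 visible leaves; their measured columns refer to the initial phase.
#'
#' @param experiment Optional experiment number (1, 2 or 3) to filter on.
#' @return A tibble, one row per treatment.
#' @export
chamber_treatments <- function(experiment = NULL) {
  path <- system.file("extdata", "chamber_treatments.csv", package = "larwheat")
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(experiment)) x <- x[x$experiment %in% experiment, ]
  x
}

#' Define a growth-chamber scenario
#'
#' A square-wave controlled-environment regime: constant day temperature and
#' PAR flux during the photoperiod, constant night temperature and darkness
#' otherwise. An optional swap changes the PAR flux once, when the simulated
#' (or observed) Haun stage crosses `swap_trigger_hs`.
#'
#' @param name Scenario label.
#' @param tday_c,tnight_c Day and night air temperature, degC.
#' @param par_umol PAR flux during the photoperiod, umol m-2 s-1.
#' @param photoperiod_h Photoperiod, h, in (0, 24].
#' @param duration_days Length of the generated series, days.
#' @param co2_ppm Air CO2 concentration (metadata only; no CO2 response term).
#' @param swap_par_umol,swap_trigger_hs Optional swap: new PAR flux and the
#'   Haun stage at which it is applied.
#' @return A `chamber_scenario` object.
#' @export
chamber_scenario <- function(name, tday_c, tnight_c, par_umol, photoperiod_h,
                             duration_days = 60, co2_ppm = 400,
                             swap_par_umol = NULL, swap_trigger_hs = NULL) {
  stopifnot(photoperiod_h > 0, photoperiod_h <= 24, par_umol >= 0,
            duration_days >= 1)
  if (!is.null(swap_par_umol) && (is.null(swap_trigger_hs) || swap_trigger_hs <= 0)) {
    abort("swap requires a positive trigger Haun stage",
          class = "larwheat_bad_scenario")
  }
  structure(list(name = name, tday_c = tday_c, tnight_c = tnight_c,
                 par_umol = par_umol, photoperiod_h = photoperiod_h,
                 duration_days = as.integer(duration_days), co2_ppm = co2_ppm,
                 swap_par_umol = swap_par_umol,
                 swap_trigger_hs = swap_trigger_hs),
            class = "chamber_scenario")
}

#' Chamber scenario presets from the bundled treatment table
#'
#' @param treatment Treatment name as in [chamber_treatments()] (e.g.
#'   `"HT.SD.320"`, `"LT.LD.280"`, `"280-170"`).
#' @param duration_days Length of the generated series, days.
#' @return A [chamber_scenario()].
#' @export
chamber_preset <- function(treatment, duration_days = 60) {
  tab <- chamber_treatments()
  row <- tab[tab$treatment == treatment, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown treatment '%s'", treatment),
          class = "larwheat_bad_scenario")
  }
  chamber_scenario(
    name = row$treatment, tday_c = row$tday_c, tnight_c = row$tnight_c,
    par_umol = row$par_umol_m2_s, photoperiod_h = row$photoperiod_h,
    duration_days = duration_days, co2_ppm = row$co2_ppm,
    swap_par_umol = if (is.na(row$swap_par_umol_m2_s)) NULL else row$swap_par_umol_m2_s,
    swap_trigger_hs = if (is.na(row$swap_trigger_hs)) NULL else row$swap_trigger_hs)
}

#' Build a sub-daily weather series for a chamber scenario
#'
#' Emits the square-wave temperature and PAR series on the 144-step
#' reference discretisation, with lights on from 08:00 for `photoperiod_h`
#' hours. Because a swap is triggered by a Haun stage, not a date, the swap
#' day (if any) is supplied by the caller after a first simulation pass
#' (see [swap_day()]).
#'
#' @param scenario A [chamber_scenario()].
#' @param swap_on_day Optional 1-based day index from which the swapped PAR
#'   flux applies.
#' @return A `subdaily_weather` tibble.
#' @export
build_chamber_weather <- function(scenario, swap_on_day = NULL) {
  stopifnot(inherits(scenario, "chamber_scenario"))
  hrs <- subdaily_hours()
  lights_on <- 8
  off <- lights_on + scenario$photoperiod_h
  lit <- hrs >= lights_on & hrs < off
  if (off > 24) lit <- lit | hrs < (off - 24)  # photoperiod wraps midnight
  ndays <- scenario$duration_days
  day <- rep(seq_len(ndays), each = length(hrs))
  hour <- rep(hrs, ndays)
  lit_all <- rep(lit, ndays)
  tair <- ifelse(lit_all, scenario$tday_c, scenario$tnight_c)
  par <- ifelse(lit_all, scenario$par_umol, 0)
  if (!is.null(swap_on_day) && !is.null(scenario$swap_par_umol)) {
    swapped <- day >= swap_on_day
    par[swapped & lit_all] <- scenario$swap_par_umol
  }
  subdaily_weather(day, hour, tair, par)
}

#' First day on which a Haun-stage trajectory crosses a trigger stage
#'
#' Helper for two-pass swap scenarios: simulate the pre-swap conditions,
#' locate the day the trigger stage is reached, then rebuild the weather with
#' [build_chamber_weather()] and `swap_on_day`.
#'
#' @param trajectory A `haun_trajectory` (see [simulate_haun()]).
#' @param trigger_hs Haun stage triggering the swap.
#' @return 1-based day index, or `NA` if the stage is never reached.
#' @export
swap_day <- function(trajectory, trigger_hs) {
  i <- which(trajectory$haun_stage >= trigger_hs)
  if (length(i) == 0) NA_integer_ else trajectory$day[i[1]]
}

#' Define a synthetic field-weather scenario
#'
#' Multi-sowing field forcing built from sinusoidal annual cycles plus
#' independent Gaussian day-to-day noise. Daily mean temperature follows
#' `annual_mean + annual_amp * cos(2 pi (doy - temp_peak_doy) / 365)`;
#' minima and maxima sit half the diurnal amplitude either side. Daily PAR
#' follows the same form around `par_mean` with its own peak day and is
#' truncated at 0. Radiation peaking near the solstice while temperature
#' peaks several weeks later reproduces the field asymmetry that makes
#' spring crops bright-and-cool (high PTQ) and autumn crops dim-and-warm
#' (low PTQ). Southern-hemisphere sites shift both seasonal phases by 182 d.
#'
#' Defaults are a hot low-desert spring-wheat site; `field_preset()` provides
#' them by name.
#'
#' @param latitude Degrees, positive north.
#' @param sowing_doys Integer vector of sowing days of year.
#' @param annual_mean,annual_amp Annual mean and half-amplitude of daily mean
#'   temperature, degC.
#' @param diurnal_amp Mean daily tmax - tmin, degC.
#' @param temp_noise_sd SD of Gaussian noise on daily mean temperature, degC.
#' @param par_mean,par_amp Annual mean and half-amplitude of daily PAR,
#'   mol m-2 d-1.
#' @param par_noise_sd SD of Gaussian noise on daily PAR, mol m-2 d-1.
#' @param temp_peak_doy,par_peak_doy Northern-hemisphere phase: day of year of
#'   the temperature and radiation maxima.
#' @param season_days Days of weather generated after each sowing.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `field_scenario` object.
#' @export
field_scenario <- function(latitude = 33.07,
                           sowing_doys = c(15, 60, 105, 150, 195, 240, 285, 330),
                           annual_mean = 22, annual_amp = 10.5,
                           diurnal_amp = 17, temp_noise_sd = 1.5,
                           par_mean = 45, par_amp = 22, par_noise_sd = 3,
                           temp_peak_doy = 205, par_peak_doy = 172,
                           season_days = 240, seed = 1L) {
  stopifnot(abs(latitude) <= 66, length(sowing_doys) >= 1)
  structure(list(latitude = latitude, sowing_doys = as.integer(sowing_doys),
                 annual_mean = annual_mean, annual_amp = annual_amp,
                 diurnal_amp = diurnal_amp, temp_noise_sd = temp_noise_sd,
                 par_mean = par_mean, par_amp = par_amp,
                 par_noise_sd = par_noise_sd, temp_peak_doy = temp_peak_doy,
                 par_peak_doy = par_peak_doy,
                 season_days = as.integer(season_days), seed = as.integer(seed)),
            class = "field_scenario")
}

#' Field-scenario presets
#'
#' `"hsc-like"`: a hot low-desert spring-wheat site (latitude 33 N) with
#' eight sowings spread over the year, emulating a serial-sowing experiment
#' whose per-sowing mean PTQ spans roughly 1.2-3.8 mol m-2 degCd-1.
#' `"nz2020-like"`: a cool temperate southern site (latitude 43.75 S) with
#' late-summer to mid-autumn sowings.
#'
#' @param name Preset name.
#' @param seed Integer seed passed to [field_scenario()].
#' @return A [field_scenario()].
#' @export
field_preset <- function(name = c("hsc-like", "nz2020-like"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "hsc-like" = field_scenario(seed = seed),
    "nz2020-like" = field_scenario(
      latitude = -43.75, sowing_doys = c(55, 75, 95, 115),
      annual_mean = 11.5, annual_amp = 5.5, diurnal_amp = 9.5,
      temp_noise_sd = 1.5, par_mean = 30, par_amp = 19, par_noise_sd = 3,
      season_days = 330, seed = seed))
}

seasonal_phase <- function(doy, peak_doy, southern) {
  if (southern) peak_doy <- peak_doy + 182
  cos(2 * pi * (doy - peak_doy) / 365)
}

#' Generate synthetic daily field weather for every sowing
#'
#' @param scenario A [field_scenario()].
#' @return Named list of `daily_weather` tibbles, one per sowing day of year
#'   (names `"sow<doy>"`), each starting at the sowing date of a non-leap
#'   reference year and extending `season_days` days.
#' @export
build_field_weather <- function(scenario) {
  stopifnot(inherits(scenario, "field_scenario"))
  southern <- scenario$latitude < 0
  out <- list()
  for (i in seq_along(scenario$sowing_doys)) {
    sow <- scenario$sowing_doys[i]
    # independent substream per sowing so adding sowings never reshuffles others
    set.seed(scenario$seed * 1000L + sow)
    date <- as.Date("2021-01-01") + (sow - 1) + seq_len(scenario$season_days) - 1
    doy <- as.integer(strftime(date, "%j"))
    tmean <- scenario$annual_mean +
      scenario$annual_amp * seasonal_phase(doy, scenario$temp_peak_doy, southern) +
      rnorm(length(doy), 0, scenario$temp_noise_sd)
    par <- scenario$par_mean +
      scenario$par_amp * seasonal_phase(doy, scenario$par_peak_doy, southern) +
      rnorm(length(doy), 0, scenario$par_noise_sd)
    par <- pmax(par, 0.5)
    out[[paste0("sow", sow)]] <- daily_weather(
      date = date,
      tmin_c = tmean - scenario$diurnal_amp / 2,
      tmax_c = tmean + scenario$diurnal_amp / 2,
      par_mol_m2 = par,
      latitude = scenario$latitude)
  }
  out
}
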