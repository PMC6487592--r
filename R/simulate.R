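#' Simulation configuration
#'
#' @param leaf_cap Final main-stem leaf number at which simulation stops.
#' @param switch_stage Haun stage at which the developmental temperature
#'   source switches from the soil-surface proxy to the canopy proxy
#'   (default 4).
#' @param start_hs Haun stage assigned at crop emergence (default 0).
#' @return A `sim_config` object.
#' @export
sim_config <- function(leaf_cap = 14, switch_stage = 4, start_hs = 0) {
  stopifnot(leaf_cap > switch_stage, switch_stage > 0, start_hs >= 0)
  structure(list(leaf_cap = leaf_cap, switch_stage = switch_stage,
                 start_hs = start_hs),
            class = "sim_config")
}

#' Choose the developmental temperature series for a given Haun stage
#'
#' Until the switch stage the apex sits near the soil surface, so a
#' soil-proxy temperature series is preferred; afterwards the canopy proxy.
#' Falls back to the air series (always present) with a one-time warning
#' when the preferred series is missing.
#'
#' @param hs Current Haun stage.
#' @param config A [sim_config()].
#' @param sources Character vector of available series ids; must contain
#'   `"air"`, may contain `"soil"` and `"canopy"`.
#' @return One of `"soil"`, `"canopy"`, `"air"`.
#' @export
select_temperature_source <- function(hs, config = sim_config(),
                                      sources = "air") {
  stopifnot("air" %in% sources)
  wanted <- if (hs < config$switch_stage) "soil" else "canopy"
  if (wanted %in% sources) return(wanted)
  warn(sprintf("'%s' temperature series unavailable; falling back to air",
               wanted),
       class = "larwheat_temperature_fallback")
  "air"
}

new_haun_trajectory <- function(df) {
  class(df) <- c("haun_trajectory", class(tibble()))
  df
}

#' Simulate a Haun-stage trajectory
#'
#' Daily-step simulation of main-stem leaf appearance from emergence
#' (`start_hs`) until the leaf cap or the end of the weather series:
#' `HS(t+1) = HS(t) + LAR(t) * dTT(t)`, with daily thermal time `dTT`
#' integrated sub-daily by [daily_forcing()]. The LAR driver depends on the
#' model class:
#'
#' * `m1_params`: constant `1 / phyllochron`;
#' * `m2_params`: phase- and sowing-date-dependent phyllochron, the rank of
#'   the currently appearing leaf being `floor(HS) + 1`;
#' * `m3_params`: carbon supply/demand. Each day the canopy green area index
#'   is either taken from `gai_series` or grown internally in proportion to
#'   Haun stage; incident PAR is attenuated through
#'   [light_interception_fraction()]; intercepted PAR and thermal time are
#'   summed over the trailing window of `d` degC d (all available history
#'   while younger than the window, minimum one day) and their ratio drives
#'   [m3_lar()] together with [effective_gai()]. The windowed mean GAI is
#'   thermal-time weighted.
#'
#' @param weather A `subdaily_weather` or `daily_weather` series.
#' @param model An [m1_params()], [m2_params()] or [m3_params()] object.
#' @param config A [sim_config()].
#' @param resp A [temperature_response()].
#' @param sowing_doy Sowing day of year (used by the M2 sowing correction;
#'   taken from the weather dates when available).
#' @param gai_series Optional numeric vector of observed GAI, one value per
#'   weather day, overriding the internal GAI trajectory (M3 only).
#' @return A `haun_trajectory` tibble with one row per simulated day:
#'   `day`, `date` (if known), `tt_cd` (that day's thermal time), `tt_cum_cd`
#'   (cumulative since emergence), `haun_stage` (at the end of the day),
#'   `lar` (used that day), and for M3 `gai`, `gai_eff` and `ptq_int` (the
#'   windowed intercepted-PAR-to-thermal-time ratio).
#' @examples
#' w <- build_chamber_weather(chamber_preset("HT.SD.320", duration_days = 30))
#' simulate_haun(w, m1_params(phyllochron = 100))
#' @export
simulate_haun <- function(weather, model, config = sim_config(),
                          resp = temperature_response(), sowing_doy = NULL,
                          gai_series = NULL) {
  stopifnot(inherits(model, "lar_model"), inherits(config, "sim_config"))
  forcing <- daily_forcing(weather, resp)
  n <- nrow(forcing)
  has_date <- "date" %in% names(forcing)
  if (is.null(sowing_doy)) {
    sowing_doy <- if (has_date) {
      as.integer(strftime(forcing$date[1], "%j"))
    } else 1L
  }
  if (!is.null(gai_series) && length(gai_series) != n) {
    abort("gai_series must have one value per weather day",
          class = "larwheat_bad_gai_series")
  }

  hs <- config$start_hs
  is_m3 <- inherits(model, "m3_params")
  haun <- lar_used <- numeric(n)
  gai <- gai_eff <- ptq_int <- rep(NA_real_, n)
  par_int <- numeric(n)
  prev_eff <- 0
  for (t in seq_len(n)) {
    tt_day <- forcing$tt_cd[t]
    if (is_m3) {
      gai_t <- if (is.null(gai_series)) {
        model$gai_per_leaf * hs * model$a_pot_juv * 1e-4 * model$pd
      } else {
        gai_series[t]
      }
      par_int[t] <- forcing$par_mol_m2[t] *
        light_interception_fraction(gai_t, model$k)
      win <- trailing_window(forcing$tt_cd[seq_len(t)], model$d)
      tt_win <- sum(forcing$tt_cd[win])
      if (tt_win <= 0) {
        abort("zero thermal time over the buffering window: development stalled",
              class = "larwheat_zero_thermal_time")
      }
      x <- sum(par_int[win]) / tt_win
      gai[t] <- gai_t
      gai_mean <- sum(gai[win] * forcing$tt_cd[win]) / tt_win
      eff <- effective_gai(hs, gai_mean, prev_eff, model)
      prev_eff <- eff
      gai_eff[t] <- eff
      ptq_int[t] <- x
      rate <- m3_lar(x, eff, model)
    } else if (inherits(model, "m2_params")) {
      rate <- m2_lar(floor(hs) + 1, sowing_doy, model)
    } else {
      rate <- m1_lar(model)
    }
    lar_used[t] <- rate
    hs <- min(hs + rate * tt_day, config$leaf_cap)
    haun[t] <- hs
    if (hs >= config$leaf_cap) {
      n <- t
      break
    }
  }
  keep <- seq_len(n)
  out <- tibble(day = forcing$day[keep],
                tt_cd = forcing$tt_cd[keep],
                tt_cum_cd = cumsum(forcing$tt_cd[keep]),
                haun_stage = haun[keep],
                lar = lar_used[keep])
  if (has_date) out <- tibble(date = forcing$date[keep], out)
  if (is_m3) {
    out$gai <- gai[keep]
    out$gai_eff <- gai_eff[keep]
    out$ptq_int <- ptq_int[keep]
  }
  new_haun_trajectory(out)
}

# indices of the trailing window holding at most `d` degCd of thermal time,
# always including the current day (minimum one whole day)
trailing_window <- function(tt_to_date, d) {
  t <- length(tt_to_date)
  acc <- 0
  first <- t
  for (i in rev(seq_len(t))) {
    acc <- acc + tt_to_date[i]
    first <- i
    if (acc >= d) break
  }
  seq.int(first, t)
}
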