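# Independent oracles used to cross-check the package implementation.
# These deliberately re-derive the arithmetic from first principles and do
# not call package internals beyond constructors.

# brute-force thermal-time integrator at arbitrary step (default 1 min):
# direct transcription of the beta response, independent of beta_response()
oracle_daily_tt <- function(day_temp, night_temp, photoperiod_h,
                            t_min = 0, t_opt = 27.5, t_max = 40,
                            step_min = 1) {
  alpha <- log(2) / log((t_max - t_min) / (t_opt - t_min))
  f <- function(temp) {
    x <- (temp - t_min) / (t_opt - t_min)
    v <- ifelse(temp <= t_min | temp >= t_max, 0,
                2 * x^alpha - x^(2 * alpha))
    pmax(0, v)
  }
  mins <- seq(step_min / 2, 24 * 60, by = step_min)
  hours <- mins / 60
  lit <- hours >= 8 & hours < (8 + photoperiod_h)
  if (8 + photoperiod_h > 24) lit <- lit | hours < (8 + photoperiod_h - 24)
  temp <- ifelse(lit, day_temp, night_temp)
  t_opt * mean(f(temp))
}

# astronomical daylength by root-finding on the solar elevation, using the
# classical declination approximation (independent of geosphere)
oracle_daylength <- function(latitude, doy) {
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  lat <- latitude * pi / 180
  elev <- function(h) {  # solar elevation (rad) at hour angle h (rad)
    asin(sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(h))
  }
  if (elev(0) <= 0) return(0)
  if (elev(pi) >= 0) return(24)
  ha <- stats::uniroot(elev, c(0, pi), tol = 1e-10)$root
  2 * ha * 24 / (2 * pi)
}

# sample a simulated trajectory into an observation tibble, optionally noisy
make_observations <- function(trajectory, every = 3, noise_sd = 0,
                              offset = 1) {
  idx <- seq(offset, nrow(trajectory), by = every)
  hs <- trajectory$haun_stage[idx]
  if (noise_sd > 0) hs <- hs + rnorm(length(idx), 0, noise_sd)
  tibble::tibble(day = trajectory$day[idx], haun_stage = pmax(hs, 0))
}
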