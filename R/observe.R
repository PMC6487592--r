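#' Haun stage from leaf measurements
#'
#' Decimal main-stem leaf stage: the number of ligulated leaves plus the
#' ratio of the length of the youngest visible (expanding) blade to the
#' length of the blade of the youngest ligulated leaf, clamped to `[0, 1]`.
#'
#' @param ligulated_count Number of ligulated leaves (>= 0).
#' @param expanding_len_cm Length of the youngest visible expanding blade, cm.
#' @param ligulated_len_cm Length of the youngest ligulated blade, cm (> 0).
#' @return Haun stage, leaves.
#' @export
haun_stage <- function(ligulated_count, expanding_len_cm, ligulated_len_cm) {
  stopifnot(all(ligulated_count >= 0), all(expanding_len_cm >= 0))
  if (any(ligulated_len_cm <= 0)) {
    abort("ligulated blade length must be > 0", class = "larwheat_bad_measurement")
  }
  ligulated_count + pmin(1, pmax(0, expanding_len_cm / ligulated_len_cm))
}

#' Initial leaf appearance rate
#'
#' Ordinary-least-squares slope of Haun stage against cumulative thermal
#' time, restricted to the early-development window (by default Haun stages
#' 1.5 to 5, before final leaf length starts increasing and confounds the
#' relationship).
#'
#' @param tt_cum_cd Cumulative thermal time, degC d.
#' @param hs Haun stage observations (same length).
#' @param hs_min,hs_max Window bounds on Haun stage (defaults 1.5 and 5).
#' @return A list: `lar_i` (leaves degCd-1), `std_error`, `n`.
#' @export
initial_lar <- function(tt_cum_cd, hs, hs_min = 1.5, hs_max = 5) {
  stopifnot(length(tt_cum_cd) == length(hs))
  keep <- hs >= hs_min & hs <= hs_max
  if (sum(keep) < 3) {
    abort(sprintf("need >= 3 observations with Haun stage in [%g, %g]",
                  hs_min, hs_max),
          class = "larwheat_too_few_points")
  }
  fit <- lm(hs[keep] ~ tt_cum_cd[keep])
  sm <- summary(fit)$coefficients
  list(lar_i = unname(coef(fit)[2]), std_error = unname(sm[2, 2]),
       n = sum(keep))
}

#' Convenience wrapper: initial LAR of a simulated trajectory
#'
#' @param trajectory A `haun_trajectory` from [simulate_haun()].
#' @param ... Passed to [initial_lar()].
#' @return As [initial_lar()].
#' @export
initial_lar_trajectory <- function(trajectory, ...) {
  initial_lar(trajectory$tt_cum_cd, trajectory$haun_stage, ...)
}

#' LAR over development from a smoothing spline
#'
#' Fits a cubic smoothing spline to Haun stage versus cumulative thermal
#' time (smoothing parameter chosen by generalised cross-validation unless
#' `spar` is given; duplicate abscissae are collapsed by averaging) and
#' returns its first derivative - the instantaneous LAR - on a uniform
#' thermal-time grid.
#'
#' @param tt_cum_cd Cumulative thermal time, degC d.
#' @param hs Haun stage observations (>= 5 points).
#' @param n_grid Number of grid points.
#' @param spar Optional smoothing parameter forwarded to
#'   [stats::smooth.spline()]; `NULL` uses GCV.
#' @return A tibble: `tt_cum_cd` (grid), `hs_fit`, `lar`.
#' @export
lar_spline <- function(tt_cum_cd, hs, n_grid = 101, spar = NULL) {
  stopifnot(length(tt_cum_cd) == length(hs))
  agg <- tapply(hs, tt_cum_cd, mean)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  if (length(x) < 5) {
    abort("need >= 5 distinct thermal-time points for a spline",
          class = "larwheat_too_few_points")
  }
  fit <- if (is.null(spar)) {
    smooth.spline(x, y, cv = FALSE)   # GCV
  } else {
    smooth.spline(x, y, spar = spar)
  }
  grid <- seq(min(x), max(x), length.out = n_grid)
  tibble(tt_cum_cd = grid,
         hs_fit = predict(fit, grid)$y,
         lar = predict(fit, grid, deriv = 1)$y)
}

#' Night consumption of carbohydrates
#'
#' `(concentration at end of day - concentration at end of night) / night
#' thermal time`, mg g-1 degCd-1. A negative value means net accumulation
#' overnight and is flagged.
#'
#' @param end_of_day_mg_g,end_of_night_mg_g Carbohydrate concentrations,
#'   mg g-1 (>= 0).
#' @param night_tt_cd Thermal time cumulated during the night, degC d (> 0).
#' @return A list: `cc_night` (mg g-1 degCd-1), `net_accumulation` (logical).
#' @export
cc_night <- function(end_of_day_mg_g, end_of_night_mg_g, night_tt_cd) {
  stopifnot(all(end_of_day_mg_g >= 0), all(end_of_night_mg_g >= 0))
  if (any(night_tt_cd <= 0)) {
    abort("night thermal time must be > 0",
          class = "larwheat_zero_thermal_time")
  }
  cc <- (end_of_day_mg_g - end_of_night_mg_g) / night_tt_cd
  list(cc_night = cc, net_accumulation = cc < 0)
}
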