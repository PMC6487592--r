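#' Asymptotic LAR-PTQ response
#'
#' Three-parameter saturating response of leaf appearance rate to the
#' photothermal quotient:
#' `LAR = LAR_min + (LAR_max - LAR_min) * PTQ / (PTQ_hf + PTQ)`.
#' `LAR_min` is the rate maintained with no radiation, `LAR_max` the
#' asymptote at unlimited supply, and `PTQ_hf` the PTQ at which LAR is
#' halfway between them.
#'
#' @param lar_min,lar_max Leaves degCd-1, `0 <= lar_min < lar_max`.
#' @param ptq_hf Half-saturation PTQ, mol m-2 degCd-1 (> 0).
#' @return A `lar_ptq_response` object.
#' @export
lar_ptq_response <- function(lar_min = 5e-3, lar_max = 22e-3, ptq_hf = 2.0) {
  if (!(lar_min >= 0 && lar_min < lar_max)) {
    abort("need 0 <= lar_min < lar_max", class = "larwheat_bad_params")
  }
  if (ptq_hf <= 0) abort("ptq_hf must be > 0", class = "larwheat_bad_params")
  structure(list(lar_min = lar_min, lar_max = lar_max, ptq_hf = ptq_hf),
            class = "lar_ptq_response")
}

#' Evaluate the LAR-PTQ response
#'
#' @param ptq Photothermal quotient(s), mol m-2 degCd-1 (>= 0).
#' @param resp A [lar_ptq_response()].
#' @return LAR, leaves degCd-1; strictly increasing in `ptq` and bounded in
#'   `[lar_min, lar_max)`.
#' @export
lar_from_ptq <- function(ptq, resp) {
  stopifnot(inherits(resp, "lar_ptq_response"), all(ptq >= 0))
  resp$lar_min + (resp$lar_max - resp$lar_min) * ptq / (resp$ptq_hf + ptq)
}

#' Fit the LAR-PTQ relationship to observed points
#'
#' Least-squares fit of initial LAR against PTQ, either linear
#' (`lar ~ a + b * ptq`, appropriate for narrow PTQ ranges) or the
#' three-parameter asymptotic form. The asymptotic fit uses
#' Levenberg-Marquardt least squares ([minpack.lm::nlsLM()]) started from
#' data-driven values. When the sampled PTQ range is too narrow to separate
#' `lar_max` from `ptq_hf` (maximum PTQ below the fitted half-saturation) the
#' fit is flagged non-identifiable.
#'
#' @param ptq,lar Paired observations.
#' @param form `"asymptotic"` or `"linear"`.
#' @return A list: `form`, `estimates` (tibble of term, estimate, std_error),
#'   `response` (a [lar_ptq_response()], asymptotic only), `fitted`,
#'   `identifiable`, and the underlying model object `fit`.
#' @export
fit_lar_ptq <- function(ptq, lar, form = c("asymptotic", "linear")) {
  form <- match.arg(form)
  stopifnot(length(ptq) == length(lar))
  n_distinct <- length(unique(ptq))
  if (form == "linear") {
    if (n_distinct < 2) {
      abort("linear fit needs >= 2 distinct PTQ values",
            class = "larwheat_singular_fit")
    }
    fit <- lm(lar ~ ptq)
    sm <- summary(fit)$coefficients
    est <- tibble(term = c("intercept", "slope"),
                  estimate = unname(sm[, 1]), std_error = unname(sm[, 2]))
    return(list(form = form, estimates = est, response = NULL,
                fitted = fitted(fit), identifiable = TRUE, fit = fit))
  }
  if (n_distinct < 3) {
    abort("asymptotic fit needs >= 3 distinct PTQ values",
          class = "larwheat_singular_fit")
  }
  start <- list(lar_min = max(1e-4, min(lar) * 0.9),
                lar_max = max(lar) * 1.2,
                ptq_hf = max(stats::median(ptq), 1e-3))
  fit <- minpack.lm::nlsLM(
    lar ~ lar_min + (lar_max - lar_min) * ptq / (ptq_hf + ptq),
    start = start,
    lower = c(lar_min = 0, lar_max = 1e-4, ptq_hf = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  sm <- summary(fit)$coefficients
  est <- tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                std_error = unname(sm[, 2]))
  cf <- coef(fit)
  identifiable <- max(ptq) >= cf[["ptq_hf"]]
  if (!identifiable) {
    warn("PTQ range too narrow to identify the asymptote (max PTQ < fitted ptq_hf)",
         class = "larwheat_nonidentifiable")
  }
  list(form = form, estimates = est,
       response = lar_ptq_response(cf[["lar_min"]], cf[["lar_max"]],
                                   cf[["ptq_hf"]]),
       fitted = fitted(fit), identifiable = identifiable, fit = fit)
}

#' Constant-phyllochron model (M1)
#'
#' @param phyllochron Thermal time per leaf, degC d (> 0).
#' @return An object of classes `m1_params`/`lar_model`.
#' @export
m1_params <- function(phyllochron = 100) {
  stopifnot(phyllochron > 0)
  structure(list(phyllochron = phyllochron),
            class = c("m1_params", "lar_model"))
}

#' M1 leaf appearance rate
#'
#' Constant in thermal time, independent of leaf rank and weather:
#' `1 / phyllochron`.
#'
#' @param params An [m1_params()].
#' @return LAR, leaves degCd-1.
#' @export
m1_lar <- function(params) {
  stopifnot(inherits(params, "m1_params"))
  1 / params$phyllochron
}

#' Sirius segmented-linear model (M2)
#'
#' Leaf production is piecewise linear in thermal time: the first three
#' leaves appear faster than leaves 4-8, and LAR slows again beyond leaf 8.
#' As a surrogate for the apex-air temperature difference of winter sowings,
#' the phyllochron of crops sown in the first 90 days of the (hemisphere-
#' adjusted) year is reduced linearly with sowing date, reaching its
#' configured maximum reduction at mid-summer day 196.
#'
#' Phase multipliers default to (0.75, 1, 1.3); they and the sowing
#' correction are varietal calibration constants, exposed here as arguments.
#'
#' @param phyllochron Base phyllochron (leaves 4-8), degC d.
#' @param phase_multipliers Length-3 positive multipliers for leaf ranks
#'   1-3, 4-8 and > 8; must be increasing (early leaves faster).
#' @param sowing_max_reduction Maximum fractional phyllochron reduction
#'   reached at `sowing_min_day`.
#' @param sowing_window Day-of-year window (inclusive) in which the
#'   correction applies.
#' @param sowing_min_day Day of year at which the ramp would reach its
#'   minimum phyllochron.
#' @param hemisphere `"north"` or `"south"`; the south shifts days by 182.
#' @return An object of classes `m2_params`/`lar_model`.
#' @export
m2_params <- function(phyllochron = 100,
                      phase_multipliers = c(0.75, 1, 1.3),
                      sowing_max_reduction = 0.25,
                      sowing_window = c(1, 90),
                      sowing_min_day = 196,
                      hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(phyllochron > 0, length(phase_multipliers) == 3,
            all(phase_multipliers > 0),
            sowing_max_reduction >= 0, sowing_max_reduction < 1)
  if (is.unsorted(phase_multipliers, strictly = TRUE)) {
    abort("phase multipliers must increase with leaf rank (early leaves faster)",
          class = "larwheat_bad_params")
  }
  structure(list(phyllochron = phyllochron,
                 phase_multipliers = phase_multipliers,
                 sowing_max_reduction = sowing_max_reduction,
                 sowing_window = sowing_window,
                 sowing_min_day = sowing_min_day,
                 hemisphere = hemisphere),
            class = c("m2_params", "lar_model"))
}

#' Sowing-date phyllochron factor for the M2 model
#'
#' @param sowing_doy Sowing day of year.
#' @param params An [m2_params()].
#' @return Multiplicative factor in `(0, 1]` applied to the phyllochron.
#' @export
m2_sowing_factor <- function(sowing_doy, params) {
  doy <- sowing_doy
  if (params$hemisphere == "south") doy <- ((doy - 182 - 1) %% 365) + 1
  if (doy < params$sowing_window[1] || doy > params$sowing_window[2]) return(1)
  ramp <- (doy - 1) / (params$sowing_min_day - 1)
  1 - params$sowing_max_reduction * min(1, ramp)
}

#' M2 leaf appearance rate
#'
#' `LAR = 1 / (phyllochron * phase_multiplier(rank) * sowing_factor)`.
#'
#' @param leaf_rank Rank of the appearing leaf (>= 1).
#' @param sowing_doy Sowing day of year.
#' @param params An [m2_params()].
#' @return LAR, leaves degCd-1.
#' @export
m2_lar <- function(leaf_rank, sowing_doy, params) {
  stopifnot(inherits(params, "m2_params"), all(leaf_rank >= 1))
  mult <- params$phase_multipliers[ifelse(leaf_rank <= 3, 1L,
                                          ifelse(leaf_rank <= 8, 2L, 3L))]
  1 / (params$phyllochron * mult * m2_sowing_factor(sowing_doy, params))
}

#' Carbon supply/demand model parameters (M3)
#'
#' LAR responds to the supply-to-demand ratio for carbon: the saturating
#' LAR-PTQ response is driven by intercepted (not incident) PAR per unit
#' thermal time, averaged over a trailing thermal-time window of `d` degC d
#' to represent the buffering capacity of stored soluble carbohydrate, and
#' is scaled by `s_c_gai / GAI_eff` so that a larger canopy (a larger carbon
#' demand) reduces the supply available per developing leaf. `GAI_eff` is
#' floored at the potential green area index of a juvenile plant with
#' `ln_eff` leaves, just after the first tiller appears, and never decreases
#' (see [effective_gai()]).
#'
#' @param response A [lar_ptq_response()].
#' @param s_c_gai Demand-scaling parameter, m2 ground m-2 leaf.
#' @param d Buffering window, degC d (default 70).
#' @param k Canopy light-extinction coefficient (default 0.45).
#' @param ln_eff Main-stem leaf number of the juvenile floor (default 3.5).
#' @param a_pot_juv Potential juvenile leaf area, cm2 leaf-1 (default 10).
#' @param pd Plant density, plants m-2 (default 150).
#' @param gai_per_leaf Dimensionless coefficient of the internal GAI
#'   trajectory `GAI = gai_per_leaf * HS * a_pot_juv * 1e-4 * pd` used when
#'   no external GAI series is supplied.
#' @param gai_form Where the demand scaling enters: `"divisor"` (default)
#'   multiplies the saturating supply term by `s_c_gai / GAI_eff`, so LAR
#'   grows without bound as GAI tends to 0 (hence the juvenile floor);
#'   `"supply"` instead scales the supply ratio inside the saturation.
#' @param pin_scale If `TRUE`, the demand scaling is pinned to 1
#'   (`s_c_gai = GAI_eff` at every step), reducing the model to the plain
#'   LAR-PTQ response driven by intercepted light - useful for algebraic
#'   checks against [lar_from_ptq()].
#' @return An object of classes `m3_params`/`lar_model`.
#' @export
m3_params <- function(response = lar_ptq_response(),
                      s_c_gai = 0.6, d = 70, k = 0.45,
                      ln_eff = 3.5, a_pot_juv = 10, pd = 150,
                      gai_per_leaf = 1,
                      gai_form = c("divisor", "supply"),
                      pin_scale = FALSE) {
  gai_form <- match.arg(gai_form)
  stopifnot(inherits(response, "lar_ptq_response"),
            s_c_gai > 0, d > 0, k > 0, ln_eff > 0, a_pot_juv > 0, pd > 0,
            gai_per_leaf > 0)
  structure(list(response = response, s_c_gai = s_c_gai, d = d, k = k,
                 ln_eff = ln_eff, a_pot_juv = a_pot_juv, pd = pd,
                 gai_per_leaf = gai_per_leaf, gai_form = gai_form,
                 pin_scale = isTRUE(pin_scale)),
            class = c("m3_params", "lar_model"))
}

#' Juvenile floor of the effective green area index
#'
#' `ln_eff * a_pot_juv * 1e-4 * pd` (m2 leaf m-2 ground): the potential GAI
#' of a plant with `ln_eff` main-stem leaves.
#'
#' @param params An [m3_params()].
#' @return GAI floor, m2 m-2.
#' @export
gai_floor <- function(params) {
  params$ln_eff * params$a_pot_juv * 1e-4 * params$pd
}

#' Effective green area index
#'
#' Demand-scaling surrogate for canopy size: while fewer than `ln_eff`
#' main-stem leaves have emerged it equals the juvenile floor
#' [gai_floor()]; afterwards it is the running maximum of the windowed mean
#' GAI (never below the floor), so it cannot decrease even if the canopy
#' senesces.
#'
#' @param ln Emerged main-stem leaf number (Haun stage).
#' @param gai_window_mean Mean GAI over the trailing buffering window.
#' @param prev_gai_eff Effective GAI at the previous step (use `0` at start).
#' @param params An [m3_params()].
#' @return Effective GAI, m2 m-2.
#' @export
effective_gai <- function(ln, gai_window_mean, prev_gai_eff = 0, params) {
  floor_gai <- gai_floor(params)
  if (ln < params$ln_eff) {
    max(floor_gai, prev_gai_eff)
  } else {
    max(floor_gai, prev_gai_eff, gai_window_mean)
  }
}

#' Fraction of incident light intercepted by the canopy
#'
#' Exponential (Beer-Lambert) attenuation: `1 - exp(-k * GAI)`.
#'
#' @param gai Green area index, m2 m-2 (>= 0).
#' @param k Extinction coefficient (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
light_interception_fraction <- function(gai, k = 0.45) {
  stopifnot(all(gai >= 0), k > 0)
  1 - exp(-k * gai)
}

#' M3 leaf appearance rate
#'
#' With `X = intercepted PAR / thermal time` accumulated over the trailing
#' buffering window (the intercepted-light analogue of PTQ):
#'
#' * `gai_form = "divisor"` (default):
#'   `LAR = lar_min + (lar_max - lar_min) * X / (ptq_hf + X) * s_c_gai / gai_eff`
#' * `gai_form = "supply"`: the supply ratio is scaled first,
#'   `X' = X * s_c_gai / gai_eff`, then `LAR = lar_min + (lar_max - lar_min) *
#'   X' / (ptq_hf + X')`.
#'
#' In both forms LAR equals `lar_min` at `X = 0` and reduces exactly to
#' [lar_from_ptq()] when `s_c_gai = gai_eff`.
#'
#' @param x_int Windowed intercepted PAR per unit thermal time,
#'   mol m-2 degCd-1 (>= 0).
#' @param gai_eff Effective GAI (> 0; the juvenile floor must prevent 0).
#' @param params An [m3_params()].
#' @return LAR, leaves degCd-1 (always >= `lar_min`).
#' @export
m3_lar <- function(x_int, gai_eff, params) {
  stopifnot(inherits(params, "m3_params"), all(x_int >= 0))
  if (any(gai_eff <= 0)) {
    abort("gai_eff must be > 0 (the juvenile floor must prevent 0)",
          class = "larwheat_zero_gai")
  }
  r <- params$response
  scale <- if (params$pin_scale) 1 else params$s_c_gai / gai_eff
  if (params$gai_form == "divisor") {
    r$lar_min + (r$lar_max - r$lar_min) * x_int / (r$ptq_hf + x_int) * scale
  } else {
    xs <- x_int * scale
    r$lar_min + (r$lar_max - r$lar_min) * xs / (r$ptq_hf + xs)
  }
}
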