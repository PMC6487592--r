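test_that("LAR-PTQ response anchors: zero supply, half-saturation, asymptote", {
  r <- lar_ptq_response(lar_min = 0.005, lar_max = 0.022, ptq_hf = 2)
  expect_equal(lar_from_ptq(0, r), 0.005)
  expect_equal(lar_from_ptq(2, r), (0.005 + 0.022) / 2)
  expect_equal(lar_from_ptq(1e6 * 2, r), 0.022, tolerance = 1e-4)
  expect_error(lar_ptq_response(0.02, 0.01, 2), class = "larwheat_bad_params")
  expect_error(lar_ptq_response(0.005, 0.02, -1), class = "larwheat_bad_params")
})

test_that("LAR-PTQ response is strictly increasing and concave", {
  r <- lar_ptq_response(0.004, 0.020, 1.5)
  ptq <- seq(0, 15, by = 0.05)
  lar <- lar_from_ptq(ptq, r)
  expect_true(all(diff(lar) > 0))
  expect_true(all(diff(diff(lar)) < 1e-12))
  expect_true(all(lar >= r$lar_min & lar < r$lar_max))
})

test_that("asymptotic fit recovers noise-free parameters", {
  truth <- lar_ptq_response(0.005, 0.022, 2.0)
  ptq <- seq(0, 15, length.out = 40)
  fit <- fit_lar_ptq(ptq, lar_from_ptq(ptq, truth), form = "asymptotic")
  expect_true(fit$identifiable)
  expect_equal(fit$response$lar_min, truth$lar_min, tolerance = 1e-6)
  expect_equal(fit$response$lar_max, truth$lar_max, tolerance = 1e-6)
  expect_equal(fit$response$ptq_hf, truth$ptq_hf, tolerance = 1e-6)
  expect_equal(nrow(fit$estimates), 3L)
  expect_true(all(fit$estimates$std_error >= 0))
})

test_that("linear fit through two points is exact; narrow range flags", {
  fit <- fit_lar_ptq(c(1, 3), c(0.006, 0.010), form = "linear")
  expect_equal(fit$estimates$estimate[fit$estimates$term == "slope"], 0.002)
  expect_equal(fit$estimates$estimate[fit$estimates$term == "intercept"], 0.004)
  # PTQ range far below the half-saturation cannot identify the asymptote
  truth <- lar_ptq_response(0.005, 0.022, 8)
  ptq <- seq(0.1, 1.2, length.out = 10)
  expect_warning(
    fit2 <- fit_lar_ptq(ptq, lar_from_ptq(ptq, truth), form = "asymptotic"),
    class = "larwheat_nonidentifiable")
  expect_false(fit2$identifiable)
  expect_error(fit_lar_ptq(c(1, 1, 1), c(1, 2, 3) * 1e-3, form = "asymptotic"),
               class = "larwheat_singular_fit")
})

test_that("noisy asymptotic fits recover parameters within 10% (median)", {
  set.seed(42)
  truth <- lar_ptq_response(0.005, 0.022, 2.0)
  ptq <- seq(0.2, 15, length.out = 40)
  clean <- lar_from_ptq(ptq, truth)
  errs <- replicate(30, {
    lar <- clean * (1 + rnorm(40, 0, 0.05))
    fit <- fit_lar_ptq(ptq, lar, form = "asymptotic")
    abs(c(fit$response$lar_min, fit$response$lar_max, fit$response$ptq_hf) -
          c(0.005, 0.022, 2.0)) / c(0.005, 0.022, 2.0)
  })
  expect_lt(stats::median(errs[1, ]), 0.10)
  expect_lt(stats::median(errs[2, ]), 0.10)
  expect_lt(stats::median(errs[3, ]), 0.10)
})

test_that("M1 LAR is the reciprocal phyllochron, independent of context", {
  expect_equal(m1_lar(m1_params(100)), 0.01)
  expect_equal(m1_lar(m1_params(90)), 1 / 90)
})

test_that("M2 phases order leaf ranks and the sowing ramp reaches its floor", {
  p <- m2_params(phyllochron = 100)
  expect_gt(m2_lar(2, 150, p), m2_lar(5, 150, p))
  expect_gt(m2_lar(5, 150, p), m2_lar(9, 150, p))
  # outside the winter-sowing window the correction is off
  expect_equal(m2_sowing_factor(150, p), 1)
  # a window reaching the minimum-phyllochron day exposes the full ramp
  p2 <- m2_params(phyllochron = 100, sowing_max_reduction = 0.25,
                  sowing_window = c(1, 200), sowing_min_day = 196)
  expect_equal(m2_sowing_factor(196, p2), 0.75)
  # hand-computed piecewise value: rank 9, winter sowing doy 45
  # factor = 1 - 0.25 * 44/195; phyllochron = 100 * 1.3 * factor
  expect_equal(m2_lar(9, 45, p),
               1 / (100 * 1.3 * (1 - 0.25 * 44 / 195)))
  # southern hemisphere mirrors dates by 182 d
  ps <- m2_params(hemisphere = "south")
  expect_equal(m2_sowing_factor(227, ps), m2_sowing_factor(45, p))
  expect_error(m2_params(phase_multipliers = c(1.3, 1, 0.75)),
               class = "larwheat_bad_params")
})

test_that("effective GAI applies the juvenile floor and never decreases", {
  p <- m3_params(ln_eff = 3.5, a_pot_juv = 10, pd = 150)
  expect_equal(gai_floor(p), 0.525)
  # below ln_eff the floor holds regardless of the windowed mean
  expect_equal(effective_gai(2, 0.1, 0, p), 0.525)
  # above ln_eff: running max of the windowed mean
  e1 <- effective_gai(5, 0.6, 0.525, p)
  e2 <- effective_gai(6, 0.8, e1, p)
  e3 <- effective_gai(7, 0.7, e2, p)  # senescing canopy
  expect_equal(c(e1, e2, e3), c(0.6, 0.8, 0.8))
})

test_that("light interception saturates exponentially with GAI", {
  expect_equal(light_interception_fraction(0), 0)
  expect_equal(light_interception_fraction(1e6), 1)
  expect_equal(light_interception_fraction(1, k = 0.45), 1 - exp(-0.45))
  expect_equal(light_interception_fraction(1, k = 0.45), 0.3624, tolerance = 1e-4)
})

test_that("M3 LAR reduces to the PTQ response when scale is unity", {
  p <- m3_params(response = lar_ptq_response(0.005, 0.022, 2), s_c_gai = 0.7)
  # s_c_gai == gai_eff: both readings collapse onto the plain response
  x <- c(0, 0.5, 2, 5, 12)
  expect_equal(m3_lar(x, 0.7, p), lar_from_ptq(x, p$response), tolerance = 1e-12)
  ps <- m3_params(response = lar_ptq_response(0.005, 0.022, 2), s_c_gai = 0.7,
                  gai_form = "supply")
  expect_equal(m3_lar(x, 0.7, ps), lar_from_ptq(x, p$response), tolerance = 1e-12)
  # zero intercepted light -> minimum rate; X = ptq_hf at unit scale -> midpoint
  expect_equal(m3_lar(0, 0.5, p), 0.005)
  expect_equal(m3_lar(2, 0.7, p), (0.005 + 0.022) / 2)
})

test_that("doubling effective GAI halves the supply term (divisor form)", {
  p <- m3_params(response = lar_ptq_response(0.005, 0.022, 2))
  x <- 1.7
  above1 <- m3_lar(x, 0.6, p) - p$response$lar_min
  above2 <- m3_lar(x, 1.2, p) - p$response$lar_min
  expect_equal(above1, 2 * above2, tolerance = 1e-12)
  expect_true(all(m3_lar(c(0, 1, 10), 0.8, p) >= p$response$lar_min))
  expect_error(m3_lar(1, 0, p), class = "larwheat_zero_gai")
})
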