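test_that("beta response hits its cardinal-temperature anchors", {
  resp <- temperature_response()
  expect_equal(beta_response(27.5, resp), 1)
  expect_equal(beta_response(0, resp), 0)
  expect_equal(beta_response(40, resp), 0)
  expect_equal(beta_response(-5, resp), 0)
  expect_equal(beta_response(45, resp), 0)
  # frozen value from an independent evaluation of the beta form at 20 degC
  expect_equal(beta_response(20, resp), 0.801816, tolerance = 1e-5)
  expect_error(beta_response(NaN, resp), class = "larwheat_bad_temperature")
  expect_error(temperature_response(10, 5, 40),
               class = "larwheat_bad_cardinals")
})

test_that("beta response is bounded, continuous and unimodal at t_opt", {
  resp <- temperature_response()
  grid <- seq(-2, 42, by = 0.01)
  f <- beta_response(grid, resp)
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(grid[which.max(f)], 27.5, tolerance = 0.011)
  expect_lt(max(abs(diff(f))), 0.005)  # no jumps on a 0.01-degC grid
  # increasing below t_opt, decreasing above, within (t_min, t_max)
  below <- grid > 0.01 & grid < 27.5
  above <- grid > 27.5 & grid < 39.99
  expect_true(all(diff(f[below]) > 0))
  expect_true(all(diff(f[above]) < 0))
})

test_that("daily thermal time matches closed forms and is additive", {
  resp <- temperature_response()
  expect_equal(daily_thermal_time(rep(27.5, 144), resp), 27.5)
  expect_equal(daily_thermal_time(rep(0, 144), resp), 0)
  # square wave, frozen from the 10-min brute-force oracle
  sq <- c(rep(28, 48), rep(24, 96))
  expect_equal(daily_thermal_time(sq, resp), 26.58084, tolerance = 1e-5)
  # additivity: two half-days recombined by weighted mean equal the full day
  half1 <- sq[1:72]; half2 <- sq[73:144]
  recombined <- (daily_thermal_time(half1, resp) +
                   daily_thermal_time(half2, resp)) / 2
  expect_equal(recombined, daily_thermal_time(sq, resp), tolerance = 1e-9)
  expect_error(daily_thermal_time(numeric(0), resp),
               class = "larwheat_empty_series")
})

test_that("thermal time agrees with a 1-min brute-force integrator", {
  set.seed(7)
  resp <- temperature_response()
  for (i in 1:50) {
    tnight <- runif(1, -2, 28)
    tday <- tnight + runif(1, 0, 14)
    pp <- round(runif(1, 4, 16) * 6) / 6   # whole 10-min cells, no midnight wrap
    hrs <- subdaily_hours()
    lit <- hrs >= 8 & hrs < (8 + pp)
    temp <- ifelse(lit, tday, tnight)
    got <- daily_thermal_time(temp, resp)
    want <- oracle_daily_tt(tday, tnight, pp)
    expect_equal(got, want, tolerance = 0.005)
  }
})

test_that("photothermal quotient reproduces the chamber treatment table", {
  # measured mean daily PAR and thermal time of the six stable
  # photothermal-effect treatments, vs their tabulated PTQ at 2 d.p.
  tab <- chamber_treatments(experiment = 1)
  tab <- tab[is.na(tab$swap_par_umol_m2_s), ]
  expect_equal(nrow(tab), 6L)
  got <- round(photothermal_quotient(tab$par_mol_m2_d, tab$tt_cd), 2)
  expect_equal(got, tab$ptq)
  expect_equal(photothermal_quotient(0, 12), 0)
  expect_error(photothermal_quotient(10, 0),
               class = "larwheat_zero_thermal_time")
  expect_error(photothermal_quotient(-1, 10),
               class = "larwheat_negative_par")
})

test_that("PTQ is homogeneous in PAR and thermal time", {
  p <- photothermal_quotient(12.4, 18.7)
  expect_equal(photothermal_quotient(24.8, 18.7), 2 * p)
  expect_equal(photothermal_quotient(12.4, 37.4), p / 2)
})

test_that("PAR flux converts to daily totals by unit arithmetic", {
  expect_equal(par_flux_to_daily(320, 8), 9.216)
  expect_equal(par_flux_to_daily(170, 16), 9.792)
  expect_equal(par_flux_to_daily(0, 12), 0)
})

test_that("daylength follows solar geometry", {
  expect_equal(day_length(0, 180), 12, tolerance = 0.2)
  expect_equal(day_length(50, 80), 12, tolerance = 0.3)
  expect_equal(day_length(-43.75, 355), oracle_daylength(-43.75, 355),
               tolerance = 0.25)
  # general agreement with the root-finding oracle over latitude and season
  for (lat in c(-60, -33, 0, 33.07, 60)) {
    for (doy in c(15, 105, 172, 260, 355)) {
      expect_equal(day_length(lat, doy), oracle_daylength(lat, doy),
                   tolerance = 0.3)
    }
  }
  expect_error(day_length(70, 100), class = "larwheat_polar_latitude")
})
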