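test_that("MSE decomposition handles exact, offset and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  ev <- mse_decomposition(x, x)
  expect_equal(c(ev$mse, ev$sb, ev$nu, ev$lc), c(0, 0, 0, 0))
  # constant offset: all error is squared bias
  ev2 <- mse_decomposition(x, x + 2)
  expect_equal(ev2$sb, 4)
  expect_equal(ev2$nu, 0, tolerance = 1e-12)
  expect_equal(ev2$lc, 0, tolerance = 1e-12)
  # zero-variance simulation: NU undefined, LC absorbs the residual
  expect_warning(ev3 <- mse_decomposition(rep(2, 5), x),
                 class = "larwheat_degenerate_slope")
  expect_true(ev3$degenerate_slope)
  expect_equal(ev3$sb + ev3$nu + ev3$lc, ev3$mse, tolerance = 1e-12)
  expect_error(mse_decomposition(1:2, 1:2), class = "larwheat_too_few_points")
})

test_that("SB + NU + LC = MSE on seeded random pairs", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    sim <- rnorm(n, 5, 2)
    obs <- sim + rnorm(n, sample(c(-1, 0, 2), 1), runif(1, 0.1, 3))
    ev <- mse_decomposition(sim, obs)
    expect_lt(abs(ev$sb + ev$nu + ev$lc - ev$mse), 1e-10)
    expect_true(ev$sb >= 0 && ev$nu >= 0 && ev$lc >= -1e-15)
    # EF consistency with MSE and observed variance
    msd_obs <- mean((obs - mean(obs))^2)
    expect_equal(ev$ef, 1 - ev$mse / msd_obs, tolerance = 1e-12)
  }
})

test_that("RMSRE matches hand arithmetic and applies the HS > 1 rule", {
  expect_equal(rmsre(c(2, 3, 4), c(2, 3, 4)), 0)
  expect_equal(rmsre(1.1 * c(2, 3, 4), c(2, 3, 4)), 10, tolerance = 1e-9)
  # hand-computed mixed vector (obs 0.5 excluded by the threshold):
  # rel errors (2.2-2)/2, (2.7-3)/3 -> sqrt(mean(0.1^2, 0.1^2)) = 10%
  expect_equal(rmsre(c(0.4, 2.2, 2.7), c(0.5, 2, 3)), 10, tolerance = 1e-9)
  expect_error(rmsre(c(1), c(0.5)), class = "larwheat_no_data")
})

test_that("Nash-Sutcliffe efficiency anchors at 1, 0 and below", {
  obs <- c(2, 4, 6, 8)
  expect_equal(nash_sutcliffe(obs, obs), 1)
  expect_equal(nash_sutcliffe(rep(mean(obs), 4), obs), 0)
  expect_lt(nash_sutcliffe(rev(obs), obs), 0)
  expect_error(nash_sutcliffe(obs, rep(3, 4)), class = "larwheat_no_variance")
})

test_that("the stage-5 selection takes the nearest value, earliest on ties", {
  expect_equal(select_hs5(c(3.1, 4.8, 5.3, 6.0)), 2L)
  expect_equal(select_hs5(c(4.9, 5.1)), 1L)
  expect_equal(select_hs5(4.2), 1L)
  expect_error(select_hs5(numeric(0)), class = "larwheat_no_data")
})

test_that("RMSRE fitting recovers an M1 phyllochron from its own output", {
  w <- build_chamber_weather(chamber_preset("HT.LD.280", duration_days = 50))
  truth <- m1_params(phyllochron = 112)
  obs <- make_observations(simulate_haun(w, truth), every = 3)
  spec <- fit_spec(list(phyllochron = c(50, 220)), seed = 7, n_starts = 4)
  fit <- estimate_params(spec, w, obs, m1_params())
  expect_equal(fit$estimates[["phyllochron"]], 112, tolerance = 0.005)
  expect_lt(fit$objective, 1e-6)
})

test_that("fitting is deterministic under a seed and order-invariant", {
  w <- build_chamber_weather(chamber_preset("HT.LD.170", duration_days = 50))
  obs <- make_observations(simulate_haun(w, m1_params(95)), every = 4)
  spec <- fit_spec(list(phyllochron = c(50, 220)), seed = 11, n_starts = 3)
  f1 <- estimate_params(spec, w, obs, m1_params())
  f2 <- estimate_params(spec, w, obs, m1_params())
  expect_identical(f1$estimates, f2$estimates)
  f3 <- estimate_params(spec, w, obs[rev(seq_len(nrow(obs))), ], m1_params())
  expect_equal(f1$estimates, f3$estimates, tolerance = 1e-9)
})

test_that("the fitted objective beats random parameter perturbations", {
  set.seed(17)
  w <- build_chamber_weather(chamber_preset("LT.LD.280", duration_days = 50))
  truth <- m1_params(phyllochron = 100)
  obs <- make_observations(simulate_haun(w, truth), every = 3)
  objective <- function(ph) {
    traj <- simulate_haun(w, m1_params(ph))   # may stop early at the leaf cap
    idx <- match(obs$day, traj$day)
    ok <- !is.na(idx)
    rmsre(traj$haun_stage[idx[ok]], obs$haun_stage[ok])
  }
  at_truth <- objective(100)
  perturbed <- vapply(runif(100, 50, 220), objective, numeric(1))
  expect_true(all(at_truth <= perturbed + 1e-12))
})
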