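# Iterated dawn/dusk map, continuous-time variant, entrainment detection,
# phase response curves and driving-period scans.

test_that("a shift-free matched oscillator keeps a constant dawn phase", {
  p <- oscillator_params(24, 24)
  sched <- driving_schedule(24, 12, 10)
  for (th0 in c(0, 0.21, 0.6, 0.99)) {
    r <- iterate_diurnal_map(th0, p, NULL, NULL, sched)
    expect_equal(r$dawn_phase, rep(th0 %% 1, 10), tolerance = 1e-12)
  }
})

test_that("the map converges to the closed-form fixed point", {
  p24 <- oscillator_params(24, 24)
  model <- linear_entrainment_model(0.5, 0.5, theta_L = 0, theta_D = 0.5,
                                    params = p24)
  fp <- entrained_fixed_point(model, 24, 12)
  expect_equal(fp$theta_dawn, 0, tolerance = 1e-10)
  expect_equal(fp$contraction, 0.25)
  sf <- as_step_functions(model)
  r <- iterate_diurnal_map(0.3, p24, sf$L, sf$D,
                           driving_schedule(24, 12, 60))
  expect_lt(abs(wrap_half_cycle(tail(r$dawn_phase_pre, 1) - fp$theta_dawn)),
            1e-10)
  # measured-type parameters
  model2 <- default_model()
  fp2 <- entrained_fixed_point(model2, 24, 12)
  sf2 <- as_step_functions(model2)
  r2 <- iterate_diurnal_map(0.7, default_params(), sf2$L, sf2$D,
                            driving_schedule(24, 12, 80))
  expect_lt(abs(wrap_half_cycle(tail(r2$dawn_phase_pre, 1) - fp2$theta_dawn)),
            1e-10)
})

test_that("map and continuous simulation agree to 1e-10 per cycle", {
  p <- default_params()
  sf <- as_step_functions(default_model())
  for (tau in c(8, 12, 15)) {
    sched <- driving_schedule(24, tau, 5)
    th0 <- 0.37
    r <- iterate_diurnal_map(th0, p, sf$L, sf$D, sched)
    # the continuous run starts just after the first dawn shift
    cs <- simulate_continuous(th0 + predict(sf$L, th0), p, sf$L, sf$D,
                              schedule = sched, dt = 0.01)
    for (k in 1:4) {
      th_cont <- cs$theta[abs(cs$time_h - k * 24) < 1e-9] %% 1
      expect_lt(abs(wrap_half_cycle(th_cont - r$dawn_phase_pre[k + 1])),
                1e-10)
    }
  }
})

test_that("with linear responses the dawn-phase error contracts by
           (1-l)(1-d) per cycle", {
  p <- default_params()
  model <- default_model(l = 0.34, d = 0.38)
  sf <- as_step_functions(model)
  fp <- entrained_fixed_point(model, 24, 12)
  contraction <- (1 - 0.34) * (1 - 0.38)
  sched <- driving_schedule(24, 12, 8)
  set.seed(10)
  for (th0 in fp$theta_dawn + runif(20, -0.2, 0.2)) {
    r <- iterate_diurnal_map(th0, p, sf$L, sf$D, sched)
    err <- abs(wrap_half_cycle(r$dawn_phase_pre - fp$theta_dawn))
    ratios <- err[3:6] / err[2:5]
    expect_equal(ratios, rep(contraction, 4), tolerance = 1e-6)
  }
})

test_that("entrainment detection uses a circular statistic", {
  expect_true(detect_stable_entrainment(rep(0.42, 6)))
  expect_false(detect_stable_entrainment(seq(0, 0.8, length.out = 6)))
  # spread of 0.005 straddling the 0/1 wrap: the naive SD is huge but the
  # circular SD is below threshold
  ph <- c(0.999, 0.001, 0.9975, 0.0025, 0.999)
  expect_gt(stats::sd(ph), 0.4)
  expect_true(detect_stable_entrainment(ph))
})

test_that("cycles-to-entrain matches direct enumeration", {
  expect_identical(cycles_to_entrain(rep(0.3, 10)), 1L)
  # geometric approach with contraction 0.25 from offset 0.4
  ph <- 0.5 + 0.4 * 0.25^(0:9)
  want <- NA_integer_
  for (n in 1:8) { # direct enumeration with the plain 3-point variance
    if (stats::var(ph[n:(n + 2)]) < 0.01) { want <- n; break }
  }
  expect_identical(cycles_to_entrain(ph), want)
  expect_false(is.na(want))
  # a non-entraining sequence never satisfies the criterion
  drift <- (0.1 + 0.37 * (0:9)) %% 1
  expect_identical(cycles_to_entrain(drift), NA_integer_)
})

test_that("continuous free run is linear in time and transitions must land on
           the grid", {
  p <- oscillator_params(24, 26)
  cs <- simulate_continuous(0.2, p, NULL, NULL, t_end = 30, dt = 0.01,
                            dark_intervals = matrix(numeric(0), ncol = 2))
  expect_equal(cs$theta, 0.2 + cs$time_h / 24, tolerance = 1e-9)
  expect_error(
    simulate_continuous(0, p, NULL, NULL, t_end = 30, dt = 0.01,
                        dark_intervals = cbind(10.005, 20)),
    "grid")
})

test_that("entrainment with measured-type parameters is reached within a few
           cycles from a wide range of phases", {
  p <- default_params()
  sf <- as_step_functions(default_model())
  for (tau in 10:14) {
    sched <- driving_schedule(24, tau, 10)
    for (th0 in seq(0, 0.9, 0.15)) {
      r <- iterate_diurnal_map(th0, p, sf$L, sf$D, sched)
      expect_true(attr(r, "entrained"))
      expect_lte(attr(r, "cycles_to_entrain"), 5)
    }
  }
})

test_that("a no-op clock has a flat dark-pulse PRC", {
  p <- oscillator_params(24, 24)
  prc <- simulate_dark_pulse_prc(p, NULL, NULL, delta = 12,
                                 pulse_starts = c(30, 36, 42), t_end = 110)
  expect_equal(prc$delta_tpk_h, rep(0, 3), tolerance = 1e-6)
})

test_that("linear step functions give a PRC that is a straight line except at
           one breakpoint", {
  p <- default_params()
  sf <- as_step_functions(default_model())
  prc <- simulate_dark_pulse_prc(p, sf$L, sf$D, delta = 12,
                                 pulse_starts = seq(26, 46, 2), t_end = 130)
  # pulses landing on the same side of the breakpoint fall on one line
  fit <- stats::lm(delta_tpk_h ~ theta_at_pulse,
                   data = prc[prc$theta_at_pulse > 0.2 &
                                prc$theta_at_pulse < 0.9, ])
  expect_lt(max(abs(stats::resid(fit))), 1e-6)
})

test_that("simulated PRC, wedge and seasonal slopes satisfy the beta-model
           identities", {
  p <- default_params()
  sf <- as_step_functions(default_model())
  prc <- simulate_dark_pulse_prc(p, sf$L, sf$D, delta = 12,
                                 pulse_starts = seq(30, 44, 2), t_end = 120)
  slope_theta <- unname(coef(stats::lm(delta_tpk_h ~ theta_at_pulse,
                                       data = prc))[2])
  beta2 <- 1 / (p$omega_L * slope_theta)
  wedge <- vapply(seq(6, 14, 2), function(d)
    simulate_dark_pulse_prc(p, sf$L, sf$D, delta = d, pulse_starts = 36,
                            t_end = 140)$delta_tpk_h, numeric(1))
  slope_delta <- unname(coef(stats::lm(wedge ~ seq(6, 14, 2)))[2])
  beta1 <- (slope_delta - 1) * beta2
  taus <- seq(10, 14, 1)
  tp <- vapply(taus, function(tau)
    utils::tail(iterate_diurnal_map(0, p, sf$L, sf$D,
                                    driving_schedule(24, tau, 100))$tpk_h, 1),
    numeric(1))
  seasonal_slope <- unname(coef(stats::lm(tp ~ taus))[2])
  expect_equal(seasonal_slope, 1 - beta1 - beta2, tolerance = 1e-8)
  expect_equal(seasonal_slope, slope_m(0.34, 0.38, 23.7 / 25.7),
               tolerance = 1e-8)
})

test_that("entrained peak time is linear in day length inside the linear
           regions", {
  p <- default_params()
  sf <- as_step_functions(default_model())
  taus <- seq(9, 15, 0.5)
  tp <- vapply(taus, function(tau)
    utils::tail(iterate_diurnal_map(0, p, sf$L, sf$D,
                                    driving_schedule(24, tau, 60))$tpk_h, 1),
    numeric(1))
  expect_gt(summary(stats::lm(tp ~ taus))$r.squared, 0.999)
})

test_that("driving-period scan flags unique-phase locking near the natural
           period and multi-valued tails far from it", {
  p <- default_params()
  sf <- as_step_functions(default_model())
  sc <- scan_driving_period(p, sf$L, sf$D,
                            periods = c(12, 21, 24, 27, 36),
                            n_cycles = 300, record_tail = 100)
  expect_identical(sc$locked, c(FALSE, TRUE, TRUE, TRUE, FALSE))
})
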