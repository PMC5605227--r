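# Trajectory normalization, sinusoidal and parabolic phase estimation,
# outlier rejection and waveform similarity.

test_that("normalization masks dark and post-dawn samples and standardizes", {
  tt <- seq(0, 71.5, 0.5)
  light <- as.numeric(tt %% 24 < 12)
  tr <- clock_trajectory(tt, sin(2 * pi * tt / 24) + 100, light, "ld")
  trn <- normalize_trajectory(tr, discard_after_lights_on = 2.5)
  # 2.5 h / 0.5 h cadence = 5 samples excluded after each dawn (t = 24, 48)
  for (dawn in c(24, 48)) {
    idx <- which(tt >= dawn & tt < dawn + 2.5)
    expect_length(idx, 5)
    expect_false(any(trn$retained[idx]))
  }
  expect_false(any(trn$retained[light == 0]))
  v <- trn$value[trn$retained]
  expect_lt(abs(mean(v)), 1e-12)
  expect_lt(abs(stats::sd(v) - 1), 1e-12)
  # affine invariance: offset and scale do not change the normalized values
  tr2 <- clock_trajectory(tt, 7 * (sin(2 * pi * tt / 24)) - 42, light, "ld2")
  trn2 <- normalize_trajectory(tr2, discard_after_lights_on = 2.5)
  expect_equal(trn2$value[trn2$retained], v, tolerance = 1e-12)
})

test_that("normalization is idempotent and rejects degenerate input", {
  tr <- noiseless_sine_traj()
  once <- normalize_trajectory(tr)
  twice <- normalize_trajectory(once)
  expect_equal(twice$value, once$value, tolerance = 1e-12)
  const <- clock_trajectory(0:10, rep(3, 11), 1, "flat")
  expect_error(normalize_trajectory(const), "zero variance")
  few <- clock_trajectory(0:5, c(1, 2, 1, 2, 1, 2), c(1, 1, 1, 0, 0, 0), "few")
  expect_error(normalize_trajectory(few), "fewer than 4")
})

test_that("sinusoid fitting recovers noiseless parameters exactly", {
  f <- fit_sinusoid(noiseless_sine_traj(T = 24, phi = 1), c(23, 25))
  expect_equal(f$amplitude, 1, tolerance = 1e-6)
  expect_equal(f$period, 24, tolerance = 1e-6)
  expect_equal(f$phase, 1, tolerance = 1e-6)
  expect_lt(f$squared_error, 1e-10)
  # arbitrary phases in [0, 2 pi), reported wrapped to (-pi, pi]
  for (phi in seq(0.1, 6.1, length.out = 8)) {
    f <- fit_sinusoid(noiseless_sine_traj(T = 23.6, phi = phi, A = 2.5,
                                          C = 1.2), c(23, 25))
    want <- ((phi + pi) %% (2 * pi)) - pi
    expect_equal(f$amplitude, 2.5, tolerance = 1e-6)
    expect_equal(f$period, 23.6, tolerance = 1e-6)
    expect_lt(abs(((f$phase - want + pi) %% (2 * pi)) - pi), 1e-6)
    expect_equal(f$baseline, 1.2, tolerance = 1e-6)
  }
})

test_that("the linear trend term is recovered", {
  f <- fit_sinusoid(noiseless_sine_traj(T = 24, phi = 1, b = 0.01),
                    c(23, 25), include_trend = TRUE)
  expect_equal(f$trend, 0.01, tolerance = 1e-4)
  expect_equal(f$period, 24, tolerance = 1e-4)
})

test_that("fixed-period fits honour the requested period", {
  f <- fit_sinusoid(noiseless_sine_traj(T = 24.5, phi = 0.4), period = 24)
  expect_equal(f$period, 24)
  expect_gt(f$squared_error, 0) # model mismatch shows up in the residual
})

test_that("shared-period fitting pools the period and keeps phases free", {
  a <- noiseless_sine_traj(T = 24.6, phi = 0, id = "a")
  b <- noiseless_sine_traj(T = 24.6, phi = pi, id = "b")
  sh <- fit_sinusoids_shared_period(list(a, b), c(23, 26))
  expect_equal(sh$period, 24.6, tolerance = 1e-6)
  dphi <- abs(sh$fits$a$phase - sh$fits$b$phase)
  expect_equal(dphi, pi, tolerance = 1e-6)
  # noisy replicates: shared period within 0.1 h of the truth
  set.seed(21)
  reps <- lapply(1:10, function(r) {
    tt <- seq(0, 96, 0.5)
    clock_trajectory(tt, sin(2 * pi * tt / 25.7 - r / 3) +
                       rnorm(length(tt), 0, 0.2), 1, paste0("r", r))
  })
  shn <- fit_sinusoids_shared_period(reps, c(23, 28))
  expect_lt(abs(shn$period - 25.7), 0.1)
})

test_that("shared-period cost is optimal at the shared optimum", {
  set.seed(5)
  trajs <- lapply(1:4, function(r) {
    tt <- seq(0, 72, 0.5)
    clock_trajectory(tt, sin(2 * pi * tt / 24.3 - r) +
                       rnorm(length(tt), 0, 0.1), 1, paste0("s", r))
  })
  sh <- fit_sinusoids_shared_period(trajs, c(23, 26))
  total_shared <- sum(vapply(sh$fits, `[[`, numeric(1), "squared_error"))
  # constraining all series to any other common period cannot do better
  for (T_alt in c(23.5, 24, 25, 25.5)) {
    total_alt <- sum(vapply(trajs, function(tr)
      fit_sinusoid(tr, period = T_alt)$squared_error, numeric(1)))
    expect_lte(total_shared, total_alt + 1e-8)
  }
})

test_that("parabolic vertex of an exact quadratic is analytic-exact", {
  tt <- seq(27, 33, 0.25)
  tr <- clock_trajectory(tt, -(tt - 30)^2, 1, "par")
  pe <- fit_peaks_parabolic(tr, window = 6)
  expect_equal(pe$peak_times, 30, tolerance = 1e-10)
})

test_that("parabolic peak-to-peak period matches a noiseless sine", {
  pe <- fit_peaks_parabolic(noiseless_sine_traj(T = 24, phi = 0,
                                                times = seq(0, 96, 0.25)))
  expect_gte(length(pe$peak_times), 3)
  expect_equal(pe$period_estimate, 24, tolerance = 1e-6)
})

test_that("parabolic peak precedes the sinusoid peak on a skewed waveform", {
  tt <- seq(0, 72, 0.25)
  y <- stepclock:::phase_waveform(tt / 24, skew = 0.3)
  trn <- normalize_trajectory(clock_trajectory(tt, y, 1, "skew"))
  f <- fit_sinusoid(trn, c(23, 25))
  pk_sin <- sinusoid_peak_time(f, near = 36)
  pe <- fit_peaks_parabolic(trn)
  pk_par <- pe$peak_times[which.min(abs(pe$peak_times - 36))]
  expect_lt(pk_par, pk_sin)
})

test_that("outlier rejection removes exactly the corrupted wells", {
  fits <- lapply(1:8, function(i) {
    f <- fit_sinusoid(noiseless_sine_traj(id = paste0("w", i)), c(23, 25))
    f
  })
  expect_identical(reject_outlier_fits(fits, 10)[1:8], fits) # all clean
  fits[[3]]$squared_error <- 11
  suppressMessages(kept <- reject_outlier_fits(fits, 10))
  expect_length(kept, 7)
  expect_identical(attr(kept, "n_rejected"), 1L)
  # synthetic 96-well plate, 5 wells corrupted with sigma = 5 noise
  set.seed(99)
  tt <- seq(0, 72, 0.5)
  plate <- lapply(1:96, function(i) {
    s <- if (i <= 5) 5 else 0.1
    fit_sinusoid(clock_trajectory(tt, sin(2 * pi * tt / 24.2 - 1) +
                                    rnorm(length(tt), 0, s), 1,
                                  paste0("w", i)), c(23, 25))
  })
  suppressMessages(kept <- reject_outlier_fits(plate, 10))
  expect_setequal(vapply(kept, `[[`, character(1), "series_id"),
                  paste0("w", 6:96))
  expect_error(reject_outlier_fits(fits, 1e-40), "all ")
})

test_that("Kendall similarity is 1 for identical and -1 for rank-reversed
           windows", {
  sched <- driving_schedule(24, 12, 1, release_time_h = 24)
  tt <- seq(0, 35.5, 0.5)
  y <- numeric(length(tt))
  base <- sin(seq(0, 1.4, length.out = sum(tt < 12))) # strictly increasing
  y[tt < 12] <- base
  y[tt >= 24] <- base
  tr <- clock_trajectory(tt, y + 10, as.numeric(tt %% 24 < 12), "same")
  tr$retained <- tr$light == 1
  attr(tr, "normalized") <- TRUE
  expect_equal(kendall_entrainment_similarity(tr, sched)$tau, 1)
  y[tt >= 24] <- rev(base) # reversal of a monotone window reverses ranks
  tr2 <- clock_trajectory(tt, y, as.numeric(tt %% 24 < 12), "rev")
  tr2$retained <- tr2$light == 1
  attr(tr2, "normalized") <- TRUE
  expect_equal(kendall_entrainment_similarity(tr2, sched)$tau, -1)
})

test_that("Kendall similarity is invariant under monotone transforms and high
           for a stably entrained synthetic trace", {
  params <- oscillator_params(24.2, 24.2)
  sf <- as_step_functions(default_model(params = params))
  sched <- driving_schedule(24, 14, 5, release_time_h = 120)
  tr <- generate_reporter_timeseries(params, sf$L, sf$D, sched, sigma = 0.05,
                                     n_series = 1, theta0 = 0.1,
                                     seed = 11)[[1]]
  trn <- normalize_trajectory(tr)
  ks <- kendall_entrainment_similarity(trn, sched)
  expect_true(all(ks$tau[2:5] > 0.8))
  # strictly monotone transform of the whole signal leaves tau unchanged
  trm <- trn
  trm$value <- exp(trn$value / 2)
  expect_equal(kendall_entrainment_similarity(trm, sched)$tau, ks$tau,
               tolerance = 1e-12)
})

test_that("dark-pulse phase shift is zero for identical sets and follows the
           stated phase formula", {
  fits <- lapply(1:4, function(r)
    fit_sinusoid(noiseless_sine_traj(T = 24, phi = 0.3,
                                     times = seq(72, 96, 0.5),
                                     id = paste0("w", r)), c(23, 25)))
  ps <- dark_pulse_phase_shift(fits, fits, t_pulse = 24, duration = 12)
  expect_equal(ps$delta_peak_h, 0, tolerance = 1e-8)
  # control phi = -pi/2, T = 24, t = 24: the trough-referenced clock phase
  # is (t/T - (phi - pi/2)/(2 pi)) mod 1 = 0.5
  f <- fit_sinusoid(noiseless_sine_traj(T = 24, phi = -pi / 2,
                                        times = seq(0, 48, 0.5)), c(23, 25))
  ps2 <- dark_pulse_phase_shift(list(f), list(f), t_pulse = 24)
  expect_equal(ps2$theta_hat, 0.5, tolerance = 1e-6)
})

test_that("dark-pulse measurements recover a generating PRC line", {
  beta <- beta_model(-1.0, 1.5, C_prc_left = -20, breakpoint = 2)
  set.seed(3)
  meas <- lapply(seq(30, 44, 2), function(tDP) {
    tt <- seq(tDP + 48, tDP + 60, 0.5)
    mk <- function(shift, id) fit_sinusoid(
      clock_trajectory(tt, -cos(2 * pi * (tt - shift) / 24) +
                         rnorm(length(tt), 0, 0.03), 1, id), period = 24)
    truth <- predict_prc(beta, (tDP / 24) %% 1, 12, 1 / 24, side = "left")
    ctrl <- lapply(1:4, function(r) mk(0, paste0("c", r)))
    pert <- lapply(1:4, function(r) mk(truth, paste0("p", r)))
    c(measured = dark_pulse_phase_shift(pert, ctrl, tDP, 12)$delta_peak_h,
      truth = truth)
  })
  m <- do.call(rbind, meas)
  # both wrapped to the principal branch before comparison
  err <- abs(stepclock::wrap_half_cycle((m[, 1] - m[, 2]) / 24) * 24)
  expect_lt(max(err), 0.2)
})

test_that("weighted regression matches exact and analytic expectations", {
  x <- 0:5
  r <- regress_slope_with_errors(x, 0.5 * x + 1)
  expect_equal(r$slope, 0.5, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$slope_sd, 0)
  # equal weights reduce to ordinary least squares
  set.seed(8)
  y <- 0.3 * x + rnorm(6, 0, 0.2)
  rw <- regress_slope_with_errors(x, y, sigma_y = rep(2, 6))
  ro <- stats::lm(y ~ x)
  expect_equal(rw$slope, unname(coef(ro)[2]), tolerance = 1e-10)
  # analytic SD for known sigma: sqrt(S / (S Sxx - Sx^2))
  S <- 6 / 4; Sx <- sum(x) / 4; Sxx <- sum(x^2) / 4
  expect_equal(rw$slope_sd, sqrt(S / (S * Sxx - Sx^2)), tolerance = 1e-12)
  expect_error(regress_slope_with_errors(rep(1, 4), 1:4), "zero spread")
})
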