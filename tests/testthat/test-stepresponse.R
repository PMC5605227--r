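# Step-response construction, linearization, phase-shift extraction and
# bootstrap uncertainty propagation.

test_that("step_phase_shift vanishes for identical reactions and follows the
           raw-phase formula", {
  tt <- seq(16, 64, 0.25)
  mk <- function(phi, T, id) fit_sinusoid(
    clock_trajectory(tt, sin(2 * pi * tt / T - phi), 1, id), period = T)
  f <- mk(0.7, 24, "c")
  for (ts in c(20, 31, 47.5)) {
    s <- step_phase_shift(f, f, ts)
    expect_equal(s$dtheta, 0, tolerance = 1e-10)
  }
  # control phi = 0, T = 24: theta at t = 12 is half a cycle
  s <- step_phase_shift(mk(0, 24, "c0"), mk(0, 24, "p0"), 12)
  expect_equal(s$theta, 0.5, tolerance = 1e-8)
})

test_that("step_phase_shift disentangles an instantaneous shift from a period
           change and ignores common offsets", {
  p <- default_params()
  t_step <- 10
  true_shift <- -0.1
  theta0 <- 0.15
  tt <- seq(t_step + 16, t_step + 64, 0.25)
  ctrl_full <- seq(0, 80, 0.25)
  ctrl <- fit_sinusoid(clock_trajectory(
    ctrl_full, -cos(2 * pi * (theta0 + p$omega_L * ctrl_full)), 1, "ctrl"),
    period = p$T_day)
  th_at <- theta0 + p$omega_L * t_step
  th_pert <- th_at + true_shift + p$omega_D * (tt - t_step)
  pert_values <- -cos(2 * pi * th_pert)
  pert <- fit_sinusoid(clock_trajectory(tt, pert_values, 1, "pert"),
                       period = p$T_night)
  s <- step_phase_shift(ctrl, pert, t_step)
  expect_equal(s$dtheta, true_shift, tolerance = 1e-3)
  # adding a common constant to both signals changes nothing: the constant
  # is absorbed in the fitted baseline
  ctrl2 <- fit_sinusoid(clock_trajectory(
    ctrl_full, -cos(2 * pi * (theta0 + p$omega_L * ctrl_full)) + 5, 1, "c2"),
    period = p$T_day)
  pert2 <- fit_sinusoid(clock_trajectory(tt, pert_values + 5, 1, "p2"),
                        period = p$T_night)
  s2 <- step_phase_shift(ctrl2, pert2, t_step)
  expect_equal(s2$dtheta, s$dtheta, tolerance = 1e-10)
})

test_that("assembled step-response functions interpolate periodically", {
  z <- assemble_step_response(list(theta = c(0, 0.3, 0.5), dtheta = c(0, 0, 0)),
                              "dawn")
  expect_equal(predict(z, runif(20)), rep(0, 20))
  F <- assemble_step_response(list(theta = c(0.2, 0.4, 0.8),
                                   dtheta = c(0.1, -0.3, 0.2)), "dusk")
  expect_equal(predict(F, 0.3), mean(c(0.1, -0.3))) # midway = node mean
  # nodes are reproduced exactly
  expect_equal(predict(F, c(0.2, 0.4, 0.8)), c(0.1, -0.3, 0.2))
  # exact periodicity
  th <- runif(50)
  expect_equal(predict(F, th + 1), predict(F, th), tolerance = 1e-12)
  expect_equal(predict(F, th - 3), predict(F, th), tolerance = 1e-12)
})

test_that("wrap-around interpolation matches an explicit unrolled interpolant", {
  F <- step_response_function(c(0.1, 0.5, 0.9), c(0.2, -0.1, 0.15), "dawn")
  xs <- c(0.1, 0.5, 0.9)
  ys <- c(0.2, -0.1, 0.15)
  unrolled <- stats::approxfun(c(xs - 1, xs, xs + 1), rep(ys, 3))
  th <- seq(0, 0.999, length.out = 211)
  expect_equal(predict(F, th), unrolled(th), tolerance = 1e-12)
  # continuity across the 1 -> 0 seam
  expect_equal(predict(F, 0.999999), predict(F, 1e-6), tolerance = 1e-4)
})

test_that("duplicate phases with conflicting shifts are an error", {
  expect_error(step_response_function(c(0.1, 0.1, 0.5), c(0.2, 0.3, 0), "dawn"),
               "conflicting")
  expect_silent(step_response_function(c(0.1, 0.1, 0.5), c(0.2, 0.2, 0),
                                       "dawn"))
  expect_error(assemble_step_response(list(theta = c(0.1, 0.1, 0.1),
                                           dtheta = c(0, 0, 0)), "dawn"),
               "3 distinct")
})

test_that("linearization recovers an exactly linear region with the stored
           sign convention", {
  # F(theta) = -0.4 (theta - 0.55) tabulated inside 6-22 CT
  th <- seq(0.3, 0.9, length.out = 9)
  F <- step_response_function(th, -0.4 * (th - 0.55), "dusk")
  lin <- linearize_step_response(F, ct_range = c(6, 22))
  expect_equal(lin$slope, 0.4, tolerance = 1e-10)
  expect_equal(lin$anchor, 0.55, tolerance = 1e-8)
  # the returned function equals the regression line inside the range
  expect_equal(predict(lin, th), -0.4 * (th - 0.55), tolerance = 1e-10)
})

test_that("the linearized function is periodic with winding 0 and one jump", {
  lin <- linear_step_params(0.34, anchor = 1 / 12, breakpoint = 7 / 12,
                            kind = "dawn")
  th <- seq(0, 1, length.out = 10000)
  v <- predict(lin, th)
  expect_lt(max(abs(v)), 1) # winding-0 magnitude bound
  expect_equal(predict(lin, th + 1), v, tolerance = 1e-12)
  # the map theta + F(theta) winds exactly once per cycle: the total
  # variation of theta + F over [0, 1] (including the breakpoint jump) is 1
  g <- th + v
  expect_equal(sum(diff(g)), 1, tolerance = 1e-9)
  # a single discontinuity, located at the breakpoint
  expect_equal(sum(abs(diff(v)) > 0.1), 1)
  expect_lt(abs(th[which(abs(diff(v)) > 0.1)] - 7 / 12), 1e-3)
})

test_that("zero-noise bootstrap members equal the point estimate and a seeded
           resample is reproducible", {
  p <- default_params()
  sf <- as_step_functions(default_model(l = 0.4, d = 0.3))
  set0 <- generate_step_experiment(p, sf$L, sf$D, sigma = 0, seed = 1)
  bs <- bootstrap_master_dataset(set0, n = 3, seed = 2)
  for (m in bs$members) {
    expect_equal(m$L_lin$slope, 0.4, tolerance = 1e-6)
    expect_equal(m$D_lin$slope, 0.3, tolerance = 1e-6)
    expect_equal(m$T_day, 23.7, tolerance = 1e-6)
    expect_equal(m$T_night, 25.7, tolerance = 1e-6)
  }
  bs2 <- bootstrap_master_dataset(set0, n = 1, seed = 7)
  bs3 <- bootstrap_master_dataset(set0, n = 1, seed = 7)
  expect_equal(bs2$members[[1]]$nodes_L, bs3$members[[1]]$nodes_L)
})

test_that("bootstrap ensemble uncertainty brackets the generating functions", {
  p <- default_params()
  sf <- as_step_functions(default_model(l = 0.4, d = 0.3))
  setn <- generate_step_experiment(p, sf$L, sf$D, sigma = 0.15, seed = 3)
  bsn <- bootstrap_master_dataset(setn, n = 60, seed = 4)
  th <- seq(0.05, 0.95, 0.05)
  for (w in c("L", "D")) {
    sm <- summarize_ensemble(bsn, th, w)
    truth <- predict(sf[[w]], th)
    covered <- mean(abs(sm$mean - truth) <= 2 * sm$sd)
    expect_gte(covered, 0.9)
  }
})

test_that("bootstrap slope distributions collapse for exact lines and track
           the analytic regression SD under jitter", {
  th <- seq(0.3, 0.9, length.out = 10)
  F0 <- step_response_function(th, -0.35 * (th - 0.6), "dusk")
  b0 <- bootstrap_slopes(F0, ct_range = c(6, 22), n = 50, seed = 1)
  expect_lt(b0$sd, 1e-10)
  expect_equal(b0$mean, 0.35, tolerance = 1e-10)
  set.seed(7)
  u <- seq(0.26, 0.9, length.out = 24)
  sh <- -0.35 * (u - 0.5) + rnorm(24, 0, 0.03)
  Fj <- step_response_function(u, sh, "dusk")
  bj <- bootstrap_slopes(Fj, ct_range = c(6, 22), n = 500, seed = 2)
  an <- regress_slope_with_errors(u, sh)
  expect_lt(abs(bj$sd / an$slope_sd - 1), 0.2)
  expect_lt(abs(bj$mean - (-an$slope)), 0.02)
})

test_that("parameter recovery: l and d from synthetic step experiments", {
  p <- default_params()
  set.seed(42)
  for (s in 1:6) {
    lt <- runif(1, 0.2, 0.6); dt_ <- runif(1, 0.2, 0.6)
    sf <- as_step_functions(default_model(l = lt, d = dt_))
    est <- estimate_step_response(
      generate_step_experiment(p, sf$L, sf$D, sigma = 0.2, seed = s))
    expect_lt(abs(est$L_lin$slope - lt), 0.05)
    expect_lt(abs(est$D_lin$slope - dt_), 0.05)
    expect_lt(abs(est$T_day / est$T_night - 23.7 / 25.7), 0.01)
  }
})

test_that("polarization-to-phosphorylation phase conversion is a 1/3-cycle
           lag and inverts cleanly", {
  expect_equal(polarization_to_phosphorylation_phase(1 / 3), 0)
  expect_equal(polarization_to_phosphorylation_phase(0), 2 / 3)
  th <- runif(20)
  back <- (polarization_to_phosphorylation_phase(th) + 1 / 3) %% 1
  expect_equal(back, th, tolerance = 1e-12)
})
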