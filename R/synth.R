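# Seeded synthetic-data generators. Every dataset shape consumed by the
# estimation pipelines can be generated from known ground truth, so each
# stage is testable by parameter recovery. The reporter waveform is
# sinusoidal in clock phase (signal = -cos(2 pi theta-hat), trough at
# phase 0); an optional skew exercises the difference between parabolic
# and sinusoidal peak estimation.

# waveform of clock phase (cycles); skew > 0 warps the phase so the peak
# arrives early in the cycle (fast rise, slow fall), as seen in purF
# reporter waveforms
phase_waveform <- function(theta, skew = 0) {
  th <- theta %% 1
  if (skew == 0) return(-cos(2 * pi * th))
  -cos(2 * pi * (th + skew * sin(pi * th)^2))
}

#' Generate driven reporter time series with known ground truth
#'
#' Evolves the phase of a ground-truth oscillator through the schedule with
#' [simulate_continuous()], renders the sinusoidal reporter waveform,
#' applies replicate Gaussian noise, emits dark samples flagged `light = 0`,
#' and optionally corrupts the first `masking_window` hours after each dawn
#' with a decaying transient so that downstream masking logic is exercised.
#'
#' @param params an [oscillator_params()].
#' @param L,D ground-truth step-response objects (may be `NULL`).
#' @param schedule a [driving_schedule()].
#' @param sigma additive Gaussian noise SD on the unit-amplitude signal.
#' @param n_series number of replicate series.
#' @param cadence sampling interval in hours (default 0.5).
#' @param t_end recording span (default: schedule span plus 72 h after
#'   release when a release is scheduled).
#' @param theta0 initial phase in cycles.
#' @param masking_amp amplitude of the post-dawn masking transient
#'   (0 disables it).
#' @param masking_window length of the corrupted window in hours.
#' @param skew waveform asymmetry (see package vignette), default 0.
#' @param seed RNG seed.
#' @return list of [clock_trajectory()] objects with attribute
#'   `truth` (list of generator inputs).
#' @export
generate_reporter_timeseries <- function(params, L, D, schedule,
                                         sigma = 0.1, n_series = 4,
                                         cadence = 0.5, t_end = NULL,
                                         theta0 = 0, masking_amp = 2,
                                         masking_window = 2.5, skew = 0,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_end))
    t_end <- if (!is.null(schedule$release_time_h))
      schedule$release_time_h + 72 else schedule$n_cycles * schedule$T_h
  dt <- 0.01
  if (abs(cadence / dt - round(cadence / dt)) > 1e-9)
    fail("cadence must be a multiple of the 0.01 h simulation step")
  sim <- simulate_continuous(theta0, params, L, D, schedule = schedule,
                             t_end = t_end, dt = dt)
  idx <- seq(1, nrow(sim), by = round(cadence / dt))
  tt <- sim$time_h[idx]
  theta <- sim$theta[idx]
  light <- sim$light[idx]
  base <- phase_waveform(theta %% 1, skew)
  dark <- schedule_dark_intervals(schedule)
  dawns <- dark[, "end"]
  dawns <- dawns[dawns < t_end]
  mask <- rep(0, length(tt))
  if (masking_amp > 0)
    for (td in dawns) {
      sel <- tt >= td & tt < td + masking_window
      mask[sel] <- mask[sel] + masking_amp * exp(-(tt[sel] - td) / 0.8)
    }
  lapply(seq_len(n_series), function(r)
    clock_trajectory(tt, base + mask + stats::rnorm(length(tt), 0, sigma),
                     light = light,
                     series_id = sprintf("synth_%02d", r),
                     schedule = schedule))
}

#' Generate a synthetic step-perturbation master dataset
#'
#' Builds a [step_experiment_set()] mirroring the in vitro protocol: one
#' control per buffer condition plus stepped reactions. A step-down
#' reaction runs at the day frequency until its step time, then shifts
#' instantaneously by the ground-truth dusk response `D` evaluated at its
#' current phase and continues at the night frequency (and conversely for
#' step-up reactions with `L`).
#'
#' @param params an [oscillator_params()].
#' @param L,D ground-truth dawn and dusk responses.
#' @param step_times_down,step_times_up step times in hours.
#' @param sigma additive noise SD.
#' @param cadence sampling interval (default 0.25 h, the
#'   fluorescence-polarization cadence).
#' @param t_end recording span (default: latest step + 64 h).
#' @param theta0 initial phase in cycles shared by all reactions (a second
#'   out-of-phase replicate set can be generated with `theta0 + 0.5`).
#' @param seed RNG seed.
#' @return a [step_experiment_set()] with attribute `truth`.
#' @export
generate_step_experiment <- function(params, L, D,
                                     step_times_down = seq(2, 24, by = 2),
                                     step_times_up = seq(2, 24, by = 2),
                                     sigma = 0.05, cadence = 0.25,
                                     t_end = NULL, theta0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_end))
    t_end <- max(step_times_down, step_times_up) + 64
  tt <- seq(0, t_end, by = cadence)
  phase_track <- function(t_step, from = c("day", "night")) {
    from <- match.arg(from)
    w1 <- if (from == "day") params$omega_L else params$omega_D
    w2 <- if (from == "day") params$omega_D else params$omega_L
    shift_fun <- if (from == "day") D else L
    th <- theta0 + w1 * pmin(tt, t_step)
    if (is.finite(t_step)) {
      th_at <- theta0 + w1 * t_step
      dth <- eval_shift(shift_fun, th_at %% 1)
      after <- tt > t_step
      th[after] <- th_at + dth + w2 * (tt[after] - t_step)
    }
    th
  }
  mk <- function(id, theta) clock_trajectory(
    tt, phase_waveform(theta %% 1) + stats::rnorm(length(tt), 0, sigma),
    light = 1, series_id = id)
  trajs <- list(mk("control_day", theta0 + params$omega_L * tt),
                mk("control_night", theta0 + params$omega_D * tt))
  meta <- data.frame(series_id = c("control_day", "control_night"),
                     role = "control", condition = c("day", "night"),
                     direction = NA_character_, step_time_h = NA_real_)
  for (i in seq_along(step_times_down)) {
    id <- sprintf("down_%02d", i)
    trajs[[length(trajs) + 1]] <- mk(id, phase_track(step_times_down[i], "day"))
    meta <- rbind(meta, data.frame(series_id = id, role = "step",
                                   condition = "night", direction = "down",
                                   step_time_h = step_times_down[i]))
  }
  for (i in seq_along(step_times_up)) {
    id <- sprintf("up_%02d", i)
    trajs[[length(trajs) + 1]] <- mk(id, phase_track(step_times_up[i], "night"))
    meta <- rbind(meta, data.frame(series_id = id, role = "step",
                                   condition = "day", direction = "up",
                                   step_time_h = step_times_up[i]))
  }
  out <- step_experiment_set(trajs, meta)
  attr(out, "truth") <- list(params = params, L = L, D = D, sigma = sigma,
                             theta0 = theta0)
  out
}

#' Generate PRC, wedge and seasonal observation sets from a beta model
#'
#' Responses are drawn from the closed-form predictions of the
#' ground-truth [beta_model()] plus replicate Gaussian noise; the reported
#' response is the replicate mean and the SEM is estimated from the
#' replicates, mirroring how the experimental tables are assembled.
#'
#' @param beta ground-truth [beta_model()] (with breakpoint set).
#' @param omega_L clock frequency in light (cycles/hour).
#' @param theta_grid PRC pulse-start phases in cycles.
#' @param delta PRC pulse duration (hours).
#' @param wedge_deltas wedge pulse durations (hours).
#' @param wedge_theta clock phase of the wedge pulses (cycles).
#' @param taus,T_hs seasonal day lengths and driving periods (crossed).
#' @param sigma replicate noise SD in hours.
#' @param n_rep replicates per condition.
#' @param sem_mode `"replicate"` (SEM estimated from the replicate spread,
#'   as experimental tables are assembled) or `"known"` (the exact
#'   `sigma/sqrt(n_rep)`, useful for calibration studies).
#' @param seed RNG seed.
#' @return list of three [observation_set()] objects (`prc`, `wedge`,
#'   `seasonal`).
#' @export
generate_prc_wedge_seasonal <- function(beta, omega_L = 1 / 24,
                                        theta_grid = seq(0.05, 0.95, by = 0.1),
                                        delta = 12,
                                        wedge_deltas = seq(2, 12, by = 2),
                                        wedge_theta = 0.25,
                                        taus = seq(8, 14, by = 2),
                                        T_hs = c(22, 24, 26),
                                        sigma = 0.5, n_rep = 4,
                                        sem_mode = c("replicate", "known"),
                                        seed = NULL) {
  sem_mode <- match.arg(sem_mode)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(mu) {
    reps <- matrix(stats::rnorm(length(mu) * n_rep, rep(mu, n_rep), sigma),
                   nrow = length(mu))
    list(mean = rowMeans(reps),
         sem = if (sem_mode == "known")
           rep(sigma / sqrt(n_rep), length(mu))
         else apply(reps, 1, stats::sd) / sqrt(n_rep))
  }
  side <- ifelse(theta_grid < (beta$breakpoint %||% 0.5), "left", "right")
  prc_mu <- predict_prc(beta, theta_grid, delta, omega_L, side = side)
  prc <- draw(prc_mu)
  wedge_mu <- predict_prc(beta, wedge_theta, wedge_deltas, omega_L,
                          intercept = "wedge")
  wed <- draw(wedge_mu)
  des <- expand.grid(tau = taus, T_h = T_hs)
  sea_mu <- predict_seasonal(beta, des$tau, des$T_h)
  sea <- draw(sea_mu)
  list(prc = observation_set("prc", prc$mean, prc$sem,
                             theta_t = theta_grid, delta = delta,
                             side = side, omega_L = omega_L),
       wedge = observation_set("wedge", wed$mean, wed$sem,
                               theta_t = wedge_theta, delta = wedge_deltas,
                               omega_L = omega_L),
       seasonal = observation_set("seasonal", sea$mean, sea$sem,
                                  tau = des$tau, T_h = des$T_h))
}
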