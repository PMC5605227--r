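# Phase-only oscillator driven by light-dark cycles: the iterated
# dawn/dusk map, a continuous-time variant, entrainment detection, phase
# response curves and driving-period scans.
#
# Phase is stored as an unwrapped accumulating value in cycles; wrapping is
# applied only when evaluating the shift functions and when reporting.

#' Free-running oscillator parameters
#'
#' @param T_day free-running period in the light (hours); default 23.7 h
#'   (the KaiABC oscillator in day buffer).
#' @param T_night free-running period in the dark (hours); default 25.7 h
#'   (night buffer).
#' @return an `oscillator_params` object with derived frequencies
#'   `omega_L = 1/T_day`, `omega_D = 1/T_night` in cycles/hour.
#' @export
oscillator_params <- function(T_day = 23.7, T_night = 25.7) {
  if (T_day <= 0 || T_night <= 0) fail("periods must be positive")
  structure(list(T_day = T_day, T_night = T_night,
                 omega_L = 1 / T_day, omega_D = 1 / T_night),
            class = "oscillator_params")
}

#' Driving light-dark schedule
#'
#' @param T_h driving period in hours.
#' @param tau_h day length (hours of light per cycle), 0 < tau < T.
#' @param n_cycles number of driving cycles.
#' @param release_time_h optional time of release into constant light.
#' @param pulses optional data frame with `start_h` and `duration_h`
#'   defining dark pulses delivered during otherwise lit spans.
#' @return a `driving_schedule` object.
#' @export
driving_schedule <- function(T_h = 24, tau_h = 12, n_cycles = 10,
                             release_time_h = NULL, pulses = NULL) {
  if (!(tau_h > 0 && tau_h < T_h)) fail("need 0 < tau_h < T_h")
  if (!is.null(pulses)) {
    pulses <- as.data.frame(pulses)
    stopifnot(all(c("start_h", "duration_h") %in% names(pulses)))
  }
  structure(list(T_h = T_h, tau_h = tau_h, n_cycles = n_cycles,
                 release_time_h = release_time_h, pulses = pulses),
            class = "driving_schedule")
}

# dark intervals [start, end) implied by a schedule over [0, t_end]
schedule_dark_intervals <- function(schedule, t_end = NULL) {
  with(schedule, {
    span <- if (!is.null(release_time_h)) release_time_h
            else n_cycles * T_h
    k <- seq_len(n_cycles)
    dark <- cbind(start = (k - 1) * T_h + tau_h, end = k * T_h)
    dark <- dark[dark[, "start"] < span, , drop = FALSE]
    dark[, "end"] <- pmin(dark[, "end"], span)
    if (!is.null(pulses) && nrow(pulses))
      dark <- rbind(dark, cbind(start = pulses$start_h,
                                end = pulses$start_h + pulses$duration_h))
    dark[order(dark[, "start"]), , drop = FALSE]
  })
}

#' Iterate the dawn/dusk phase map over driving cycles
#'
#' One driving cycle advances the oscillator phase by \eqn{\omega_L \tau}
#' during the day and \eqn{\omega_D (T - \tau)} at night, with instantaneous
#' shifts \eqn{\hat L(\hat\theta \bmod 1)} at dawn and
#' \eqn{\hat D(\hat\theta \bmod 1)} at dusk. Dawn phases are recorded
#' immediately after the dawn shift; the peak time per cycle is the time
#' after dawn at which the phase reaches 0.5 cycles,
#' \eqn{t_{pk} = ((0.5 - \hat\theta_{dawn}) \bmod 1)/\omega_L}, flagged when
#' it exceeds the day length.
#'
#' @param theta0 initial phase in cycles, taken as the phase at the first
#'   dawn before the dawn shift.
#' @param params an [oscillator_params()].
#' @param L,D dawn and dusk step-response objects (anything accepted by
#'   `predict`, or `NULL` for no shift).
#' @param schedule a pulse-free [driving_schedule()].
#' @return an `entrainment_result`: data frame with columns `cycle`,
#'   `dawn_phase` (post-shift, wrapped), `dusk_phase` (pre-shift, wrapped),
#'   `tpk_h`, `tpk_in_day`; attributes `entrained` and `cycles_to_entrain`.
#' @export
iterate_diurnal_map <- function(theta0, params, L, D, schedule) {
  if (!is.null(schedule$pulses) && nrow(schedule$pulses))
    fail("the diurnal map does not handle pulses; use simulate_continuous()")
  n <- schedule$n_cycles
  tau <- schedule$tau_h; T <- schedule$T_h
  day_adv <- tau * params$omega_L
  night_adv <- (T - tau) * params$omega_D
  dawn <- dusk <- dawn_pre <- numeric(n)
  th <- theta0
  for (k in seq_len(n)) {
    dawn_pre[k] <- th %% 1
    th <- th + eval_shift(L, th %% 1)     # dawn shift
    dawn[k] <- th %% 1
    th <- th + day_adv                    # day
    dusk[k] <- th %% 1
    th <- th + eval_shift(D, th %% 1)     # dusk shift
    th <- th + night_adv                  # night
  }
  tpk <- ((0.5 - dawn) %% 1) / params$omega_L
  res <- data.frame(cycle = seq_len(n), dawn_phase = dawn,
                    dawn_phase_pre = dawn_pre, dusk_phase = dusk,
                    tpk_h = tpk, tpk_in_day = tpk <= tau)
  structure(res,
            entrained = detect_stable_entrainment(dawn),
            cycles_to_entrain = cycles_to_entrain(dawn),
            final_phase_unwrapped = th,
            class = c("entrainment_result", "data.frame"))
}

#' Detect stable entrainment from dawn phases
#'
#' The oscillator is judged stably entrained when the circular standard
#' deviation of the dawn phases of the last five driving cycles is below
#' `threshold` cycles.
#'
#' @param dawn_phases dawn phases in cycles (at least 5).
#' @param threshold circular-SD criterion in cycles (default 0.01).
#' @return logical flag.
#' @export
detect_stable_entrainment <- function(dawn_phases, threshold = 0.01) {
  n <- length(dawn_phases)
  if (n < 5) return(NA)
  circular_sd_cycles(dawn_phases[(n - 4):n]) < threshold
}

#' Cycles needed to reach entrainment
#'
#' Computes the sliding three-cycle circular variance
#' \eqn{EC_n = var(\hat\theta_n, \hat\theta_{n+1}, \hat\theta_{n+2})} of
#' dawn phases and returns the first `n` (up to `n_max`) for which it drops
#' below `threshold`; `NA` when convergence is not reached.
#'
#' @param dawn_phases dawn phases in cycles (at least 3).
#' @param threshold variance criterion in cycles^2 (default 0.01).
#' @param n_max largest window start considered (default 8).
#' @return integer cycle index or `NA_integer_`.
#' @export
cycles_to_entrain <- function(dawn_phases, threshold = 0.01, n_max = 8) {
  n <- length(dawn_phases)
  if (n < 3) return(NA_integer_)
  for (k in seq_len(min(n_max, n - 2))) {
    if (circular_var_cycles(dawn_phases[k:(k + 2)]) < threshold)
      return(k)
  }
  NA_integer_
}

#' Continuous-time simulation of the driven phase oscillator
#'
#' Explicit fixed-step evolution: the phase advances at `omega_L` in the
#' light and `omega_D` in the dark, and shifts instantaneously by
#' \eqn{\hat L} at each dark-to-light transition and \eqn{\hat D} at each
#' light-to-dark transition (each transition applied exactly once). Every
#' transition must land on the time grid; off-grid transitions are an error
#' rather than being silently rounded.
#'
#' @param theta0 initial phase in cycles at t = 0.
#' @param params an [oscillator_params()].
#' @param L,D dawn and dusk step-response objects.
#' @param schedule a [driving_schedule()] (pulses allowed), or `NULL` for
#'   constant light with `dark_intervals` supplied directly.
#' @param t_end simulation span in hours (default: the span implied by the
#'   schedule).
#' @param dt time step in hours (default 0.01).
#' @param dark_intervals optional 2-column matrix of dark `[start, end)`
#'   intervals, overriding the schedule.
#' @return data frame with columns `time_h`, `theta` (unwrapped cycles) and
#'   `light`.
#' @export
simulate_continuous <- function(theta0, params, L, D, schedule = NULL,
                                t_end = NULL, dt = 0.01,
                                dark_intervals = NULL) {
  if (is.null(dark_intervals)) {
    if (is.null(schedule)) fail("supply a schedule or dark_intervals")
    dark_intervals <- schedule_dark_intervals(schedule)
    if (is.null(t_end))
      t_end <- if (!is.null(schedule$release_time_h))
        schedule$release_time_h else schedule$n_cycles * schedule$T_h
  }
  if (is.null(t_end)) fail("t_end required with explicit dark_intervals")
  trans <- sort(unique(c(dark_intervals)))
  trans <- trans[trans > 0 & trans < t_end]
  if (any(abs(trans / dt - round(trans / dt)) > 1e-6))
    fail("light/dark transition does not land on the dt grid; ",
         "choose dt to divide all transition times")
  n_steps <- round(t_end / dt)
  t_grid <- seq(0, by = dt, length.out = n_steps + 1)
  in_dark <- rep(FALSE, n_steps + 1)
  for (j in seq_len(nrow(dark_intervals)))
    in_dark <- in_dark | (t_grid >= dark_intervals[j, 1] - 1e-9 &
                            t_grid < dark_intervals[j, 2] - 1e-9)
  theta <- numeric(n_steps + 1)
  theta[1] <- theta0
  dL <- dt * params$omega_L
  dD <- dt * params$omega_D
  for (k in seq_len(n_steps)) {
    th <- theta[k]
    if (k > 1 && in_dark[k - 1] != in_dark[k]) {
      th <- th + if (in_dark[k]) eval_shift(D, th %% 1)
                 else eval_shift(L, th %% 1)
    }
    theta[k + 1] <- th + if (in_dark[k]) dD else dL
  }
  # a transition exactly at t_end is still applied to the recorded state
  if (n_steps >= 1 && in_dark[n_steps] != in_dark[n_steps + 1]) {
    theta[n_steps + 1] <- theta[n_steps + 1] +
      if (in_dark[n_steps + 1]) eval_shift(D, theta[n_steps + 1] %% 1)
      else eval_shift(L, theta[n_steps + 1] %% 1)
  }
  data.frame(time_h = t_grid, theta = theta, light = as.numeric(!in_dark))
}

# first time (>= after) at which the unwrapped phase crosses level + k for
# the smallest integer k making the crossing reachable; linear interpolation
# between grid points
first_phase_crossing <- function(traj, level, after = 0) {
  sel <- traj$time_h >= after
  t <- traj$time_h[sel]; th <- traj$theta[sel]
  target <- ceiling(th[1] - level) + level
  if (th[1] >= target) target <- target + 1
  i <- which(th >= target)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(t[1])
  t[i - 1] + (target - th[i - 1]) / (th[i] - th[i - 1]) * (t[i] - t[i - 1])
}

#' Simulated phase-resetting curve for a dark pulse
#'
#' For each pulse start time, simulates the oscillator in constant light
#' with a single dark pulse of length `delta` (realized as a dusk step at
#' pulse start and a dawn step at pulse end) and compares the timing of the
#' next phase-0.5 crossing (the rhythm peak) against an unpulsed control.
#'
#' @param params an [oscillator_params()].
#' @param L,D dawn and dusk step-response objects.
#' @param delta pulse duration in hours (default 12).
#' @param pulse_starts vector of pulse start times in hours.
#' @param t_end simulation span (default 120 h).
#' @param dt time step (default 0.01 h).
#' @param theta0 initial phase in cycles.
#' @return data frame with columns `pulse_start`, `theta_at_pulse` (clock
#'   phase when the pulse begins, cycles) and `delta_tpk_h` (peak-time shift,
#'   hours, wrapped to half a free-running period).
#' @export
simulate_dark_pulse_prc <- function(params, L, D, delta = 12, pulse_starts,
                                    t_end = 120, dt = 0.01, theta0 = 0) {
  ctrl <- simulate_continuous(theta0, params, L, D, t_end = t_end, dt = dt,
                              dark_intervals = matrix(numeric(0), ncol = 2))
  out <- data.frame(pulse_start = pulse_starts,
                    theta_at_pulse = NA_real_, delta_tpk_h = NA_real_)
  for (i in seq_along(pulse_starts)) {
    s <- pulse_starts[i]
    pert <- simulate_continuous(theta0, params, L, D, t_end = t_end, dt = dt,
                                dark_intervals = cbind(s, s + delta))
    out$theta_at_pulse[i] <-
      ctrl$theta[which.min(abs(ctrl$time_h - s))] %% 1
    tp <- first_phase_crossing(pert, 0.5, after = s + delta)
    tc <- first_phase_crossing(ctrl, 0.5, after = s + delta)
    out$delta_tpk_h[i] <-
      wrap_half_cycle((tp - tc) / params$T_day) * params$T_day
  }
  out
}

#' Scan driving periods for phase locking
#'
#' Simulates entrainment to symmetric light-dark cycles (day length
#' `T/2`) across a grid of driving periods and records the dawn phases
#' (immediately before the dawn shift) of the last `record_tail` cycles.
#' Unique-phase locking appears as a single-valued tail.
#'
#' @param params an [oscillator_params()].
#' @param L,D dawn and dusk step-response objects.
#' @param periods vector of driving periods in hours.
#' @param n_cycles cycles simulated per period (default 1000).
#' @param record_tail number of final cycles recorded (default 950).
#' @param theta0 initial phase in cycles.
#' @param lock_tol circular-SD threshold in cycles classifying a
#'   single-valued tail (default 0.01).
#' @return data frame with columns `period`, `locked` and `phase_spread`;
#'   the recorded tails are in attribute `tails` (list of phase vectors).
#' @export
scan_driving_period <- function(params, L, D, periods, n_cycles = 1000,
                                record_tail = 950, theta0 = 0,
                                lock_tol = 0.01) {
  record_tail <- min(record_tail, n_cycles)
  tails <- vector("list", length(periods))
  spread <- numeric(length(periods))
  for (i in seq_along(periods)) {
    T <- periods[i]
    tau <- T / 2
    day_adv <- tau * params$omega_L
    night_adv <- (T - tau) * params$omega_D
    th <- theta0
    rec <- numeric(record_tail)
    j <- 0L
    for (k in seq_len(n_cycles)) {
      if (k > n_cycles - record_tail) {
        j <- j + 1L
        rec[j] <- th %% 1 # dawn phase before the L shift
      }
      th <- th + eval_shift(L, th %% 1) + day_adv
      th <- th + eval_shift(D, th %% 1) + night_adv
    }
    tails[[i]] <- rec
    spread[i] <- circular_sd_cycles(rec)
  }
  structure(data.frame(period = periods, locked = spread < lock_tol,
                       phase_spread = spread),
            tails = tails)
}
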