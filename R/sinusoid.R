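# Sinusoidal regression of rhythm time series.
#
# The model is y = A sin(2 pi t / T - phi) + b t + C. For a fixed period T
# the model is linear in (A cos phi, -A sin phi, b, C), so the least-squares
# problem is solved exactly by linear regression on a sine/cosine basis; the
# period is then profiled on a grid over its bounds and polished with
# one-dimensional minimization. This finds the global minimum of the cost
# without multi-start heuristics.

# exact least squares at fixed period; returns coefficients and SSE
sinusoid_ls_fixed_T <- function(x, y, T, include_trend = FALSE) {
  s <- sin(2 * pi * x / T)
  c_ <- cos(2 * pi * x / T)
  X <- if (include_trend) cbind(s = s, c = c_, b = x, C = 1)
       else cbind(s = s, c = c_, C = 1)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  sse <- sum(fit$residuals^2)
  list(a = cf[["s"]], b2 = cf[["c"]],
       trend = if (include_trend) cf[["b"]] else 0,
       baseline = cf[["C"]], sse = sse)
}

new_sinusoid_fit <- function(coefs, T, n, id) {
  a <- coefs$a; b2 <- coefs$b2
  A <- sqrt(a^2 + b2^2)
  # y = a sin + b2 cos = A sin(2 pi t/T - phi) with a = A cos phi,
  # b2 = -A sin phi
  phi <- atan2(-b2, a)
  if (phi <= -pi) phi <- phi + 2 * pi # report phi in (-pi, pi]
  structure(list(amplitude = A, period = T, phase = phi,
                 trend = coefs$trend, baseline = coefs$baseline,
                 squared_error = coefs$sse, n_points = n,
                 series_id = id, converged = TRUE),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sinusoid_fit '%s': A=%.3f T=%.3f h phi=%.3f rad C=%.3f sse=%.3g n=%d>\n",
    x$series_id, x$amplitude, x$period, x$phase, x$baseline,
    x$squared_error, x$n_points))
  invisible(x)
}

# profile the summed SSE over the period within bounds: coarse grid then
# golden-section polish in the bracketing interval
profile_period <- function(sse_fun, bounds, n_grid = 201) {
  Ts <- seq(bounds[1], bounds[2], length.out = n_grid)
  sses <- vapply(Ts, sse_fun, numeric(1))
  i <- which.min(sses)
  lo <- Ts[max(1, i - 1)]
  hi <- Ts[min(n_grid, i + 1)]
  opt <- stats::optimize(sse_fun, interval = c(lo, hi), tol = 1e-10)
  if (opt$objective <= sses[i]) opt$minimum else Ts[i]
}

#' Fit a sinusoid to a trajectory
#'
#' Least-squares fit of \eqn{y = A \sin(2\pi t/T - \phi) + b t + C} to the
#' retained samples of a trajectory. The period is either fixed or
#' constrained within `period_bounds` (default 23-25 h, the circadian range
#' used for free-running reporter rhythms).
#'
#' @param traj a [clock_trajectory()] (normalized), or any data frame with
#'   `time_h` and `value` columns.
#' @param period_bounds length-2 numeric, lower and upper bound on T (hours).
#' @param period optional fixed period; overrides `period_bounds`.
#' @param include_trend logical, include the linear drift term `b t`.
#' @return a `sinusoid_fit` object with elements `amplitude`, `period`,
#'   `phase` (radians, in (-pi, pi]), `trend`, `baseline`, `squared_error`,
#'   `n_points`, `series_id`.
#' @export
fit_sinusoid <- function(traj, period_bounds = c(23, 25), period = NULL,
                         include_trend = FALSE) {
  xy <- retained_xy(traj)
  if (length(xy$x) < 4)
    fail("series '", xy$id, "': too few points for sinusoidal regression")
  if (is.null(period)) {
    if (length(period_bounds) != 2 || period_bounds[1] >= period_bounds[2])
      fail("period_bounds must be c(lo, hi) with lo < hi")
    sse_fun <- function(T)
      sinusoid_ls_fixed_T(xy$x, xy$y, T, include_trend)$sse
    period <- profile_period(sse_fun, period_bounds)
  }
  new_sinusoid_fit(sinusoid_ls_fixed_T(xy$x, xy$y, period, include_trend),
                   period, length(xy$x), xy$id)
}

#' Fit sinusoids to several trajectories with one shared period
#'
#' Amplitude, phase and baseline are fit independently per series, but a
#' single best-fit period minimizes the summed squared error over all
#' series, as appropriate when replicate reactions share one buffer
#' condition.
#'
#' @param trajs list of trajectories (see [fit_sinusoid()]).
#' @param period_bounds length-2 numeric bounds on the shared period (hours).
#' @param include_trend logical, include per-series linear drift.
#' @return list with elements `period` (the shared period) and `fits`
#'   (list of `sinusoid_fit`, one per series, named by series id).
#' @export
fit_sinusoids_shared_period <- function(trajs, period_bounds = c(20, 30),
                                        include_trend = FALSE) {
  if (length(trajs) < 1) fail("need at least one trajectory")
  xys <- lapply(trajs, retained_xy)
  sse_fun <- function(T)
    sum(vapply(xys, function(xy)
      sinusoid_ls_fixed_T(xy$x, xy$y, T, include_trend)$sse, numeric(1)))
  T_hat <- profile_period(sse_fun, period_bounds)
  fits <- lapply(xys, function(xy)
    new_sinusoid_fit(sinusoid_ls_fixed_T(xy$x, xy$y, T_hat, include_trend),
                     T_hat, length(xy$x), xy$id))
  names(fits) <- vapply(xys, `[[`, character(1), "id")
  list(period = T_hat, fits = fits)
}

#' Peak time of a fitted sinusoid
#'
#' The fitted waveform peaks where \eqn{2\pi t/T - \phi = \pi/2 \pmod{2\pi}}.
#'
#' @param fit a `sinusoid_fit`.
#' @param near optional time in hours; the peak nearest to it is returned.
#'   By default the first peak at `t >= 0`.
#' @return peak time in hours.
#' @export
sinusoid_peak_time <- function(fit, near = NULL) {
  t0 <- fit$period * (fit$phase / (2 * pi) + 0.25)
  if (is.null(near)) return(t0 %% fit$period)
  t0 + round((near - t0) / fit$period) * fit$period
}

#' Clock phase of a fitted rhythm at a given time
#'
#' Converts the fitted sinusoid phase to the clock-phase convention
#' (theta-hat = 0 at the rhythm trough, 0.5 at the peak):
#' \eqn{\hat\theta(t) = t/T - (\phi - \pi/2)/(2\pi) \bmod 1}.
#'
#' @param fit a `sinusoid_fit`.
#' @param t time in hours.
#' @return clock phase in cycles, in [0, 1).
#' @export
clock_phase_at <- function(fit, t) {
  (t / fit$period - (fit$phase - pi / 2) / (2 * pi)) %% 1
}

# raw oscillation phase theta = 2 pi t/T - phi, in cycles (used when
# comparing a perturbed and a control reaction at the same lab time)
raw_phase_at <- function(fit, t) (t / fit$period - fit$phase / (2 * pi)) %% 1
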