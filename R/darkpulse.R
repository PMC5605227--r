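# Phase shifts caused by dark pulses delivered in otherwise constant light,
# and weighted linear regression with known errors in y.

#' Phase shift in response to a dark pulse
#'
#' Computes the peak-time displacement between replicate perturbed wells and
#' replicate control wells, \eqn{\Delta t_{pk} = \bar t_{pk,DP} - \bar
#' t_{pk,LL}}, and the clock phase at which the pulse began, estimated from
#' the mean control phase and period. Fits should be restricted to the
#' 36-48 h window after the end of the pulse before calling this function
#' (see [window_trajectory()]), so that transients have decayed.
#'
#' Peak times of individual wells are referenced to the same cycle before
#' averaging: each is wrapped to within half a period of the first control
#' well's peak.
#'
#' @param perturbed_fits,control_fits lists of `sinusoid_fit` objects for
#'   the pulsed and unpulsed wells.
#' @param t_pulse pulse start time in hours.
#' @param duration pulse length in hours.
#' @return a `phase_shift_measurement`: list with `t_perturbation`,
#'   `theta_hat` (clock phase at pulse start, cycles in [0,1)),
#'   `delta_peak_h`, `sd_perturbed`, `sd_control`, `sd_delta`, `duration`.
#' @export
dark_pulse_phase_shift <- function(perturbed_fits, control_fits,
                                   t_pulse, duration = 12) {
  if (!length(perturbed_fits) || !length(control_fits))
    fail("both perturbed and control fit sets must be non-empty")
  T_bar <- mean(vapply(control_fits, `[[`, numeric(1), "period"))
  ref <- sinusoid_peak_time(control_fits[[1]],
                            near = t_pulse + duration + 42)
  pk <- function(f) sinusoid_peak_time(f, near = ref)
  pk_ctrl <- vapply(control_fits, pk, numeric(1))
  pk_pert <- vapply(perturbed_fits, pk, numeric(1))
  delta <- mean(pk_pert) - mean(pk_ctrl)
  delta <- wrap_half_cycle(delta / T_bar) * T_bar
  phi_bar <- Arg(mean(exp(1i * vapply(control_fits, `[[`, numeric(1),
                                      "phase"))))
  theta_hat <- (t_pulse / T_bar - (phi_bar - pi / 2) / (2 * pi)) %% 1
  structure(list(t_perturbation = t_pulse,
                 theta_hat = theta_hat,
                 delta_peak_h = delta,
                 sd_perturbed = stats::sd(pk_pert),
                 sd_control = stats::sd(pk_ctrl),
                 sd_delta = sqrt(stats::var(pk_pert) / length(pk_pert) +
                                   stats::var(pk_ctrl) / length(pk_ctrl)),
                 duration = duration,
                 period_control = T_bar),
            class = "phase_shift_measurement")
}

#' Linear regression with known errors in the dependent variable
#'
#' Weighted least squares with weights \eqn{1/\sigma_i^2} and the standard
#' analytic formulas for the slope and intercept standard deviations. When
#' `sigma_y` is absent the fit is ordinary least squares and parameter SDs
#' are estimated from the residual variance.
#'
#' @param x,y numeric vectors (at least 2 points).
#' @param sigma_y optional per-point SDs of `y`, all positive.
#' @return list with `slope`, `slope_sd`, `intercept`, `intercept_sd`.
#' @export
regress_slope_with_errors <- function(x, y, sigma_y = NULL) {
  n <- length(x)
  if (n < 2 || length(y) != n) fail("need at least 2 (x, y) points")
  if (diff(range(x)) == 0) fail("degenerate regression: x has zero spread")
  if (is.null(sigma_y)) {
    fit <- stats::lm(y ~ x)
    cf <- stats::coef(fit)
    # exact fits have zero residuals hence zero SD
    se <- if (n > 2 && sum(stats::resid(fit)^2) > 1e-24)
      sqrt(diag(stats::vcov(fit))) else c(0, 0)
    return(list(slope = unname(cf[2]), slope_sd = unname(se[2]),
                intercept = unname(cf[1]), intercept_sd = unname(se[1])))
  }
  if (any(sigma_y <= 0)) fail("sigma_y must be positive")
  w <- 1 / sigma_y^2
  S <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x^2); Sxy <- sum(w * x * y)
  Delta <- S * Sxx - Sx^2
  list(slope = (S * Sxy - Sx * Sy) / Delta,
       slope_sd = sqrt(S / Delta),
       intercept = (Sxx * Sy - Sx * Sxy) / Delta,
       intercept_sd = sqrt(Sxx / Delta))
}
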