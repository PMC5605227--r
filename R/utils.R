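# Phase arithmetic and circular statistics used throughout the package.
# Phases are stored in cycles (1 cycle = 2*pi rad = one full oscillation).
# The clock-phase convention: theta_hat = 0 at the trough of the rhythm
# (CT 0), theta_hat = 0.5 at the peak, with CT labelled at 24 h/cycle.

#' Wrap a phase to the fundamental interval [0, 1)
#'
#' @param x numeric vector of phases in cycles.
#' @return `x` modulo 1.
#' @export
wrap_cycle <- function(x) x %% 1

#' Wrap a phase difference to (-0.5, 0.5] cycles
#'
#' Used for phase shifts under the winding-number-0 convention: an
#' instantaneous shift is always reported on the branch nearest zero.
#'
#' @param x numeric vector of phase differences in cycles.
#' @return wrapped differences in (-0.5, 0.5].
#' @export
wrap_half_cycle <- function(x) {
  w <- x %% 1
  w[w > 0.5] <- w[w > 0.5] - 1
  w
}

# wrap a radian angle difference to (-pi, pi]
wrap_half_rad <- function(x) wrap_half_cycle(x / (2 * pi)) * 2 * pi

# unwrap a phase (cycles) onto the branch [bp - 1, bp): the unique
# representative congruent to x mod 1 lying in that half-open interval
unwrap_to_branch <- function(x, breakpoint) {
  bp <- breakpoint %% 1
  f <- x %% 1
  f - (f >= bp)
}

#' Circular mean of phases in cycles
#' @param theta phases in cycles.
#' @return mean phase in [0, 1).
#' @export
circular_mean_cycles <- function(theta) {
  z <- mean(exp(2i * pi * theta))
  (Arg(z) / (2 * pi)) %% 1
}

#' Circular standard deviation of phases in cycles
#'
#' Computed as sqrt(-2 log Rbar)/(2 pi), the standard wrapped-normal
#' estimator, so that phases straddling the 0/1 wrap are handled correctly.
#'
#' @param theta phases in cycles.
#' @return circular SD in cycles.
#' @export
circular_sd_cycles <- function(theta) {
  rbar <- Mod(mean(exp(2i * pi * theta)))
  rbar <- min(rbar, 1)
  sqrt(-2 * log(rbar)) / (2 * pi)
}

# sample variance (n - 1 denominator) of deviations from the circular
# mean, deviations wrapped to (-0.5, 0.5]; in cycles^2
circular_var_cycles <- function(theta) {
  mu <- circular_mean_cycles(theta)
  stats::var(wrap_half_cycle(theta - mu))
}

#' Convert circadian-time hours to phase in cycles
#'
#' CT labelling is fixed at 24 h per cycle regardless of the
#' condition-specific free-running periods; CT 0 is the rhythm trough.
#'
#' @param ct hours of circadian time.
#' @return phase in cycles (not wrapped).
#' @export
ct_to_cycles <- function(ct) ct / 24

#' Convert phase in cycles to circadian-time hours
#' @param theta phase in cycles.
#' @return CT hours.
#' @export
cycles_to_ct <- function(theta) theta * 24

# internal: stop() with a call.-free message
fail <- function(...) stop(..., call. = FALSE)
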