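# Dawn (L) and dusk (D) step-response functions: tabulated periodic
# phase-shift curves, their linearization, and phase-shift extraction from
# step-perturbation experiments.

#' Construct a tabulated step-response function
#'
#' A step-response function maps the clock phase at which an environmental
#' step occurs to the instantaneous phase shift it causes. It is represented
#' by nodes on the unit circle and evaluated by piecewise-linear,
#' 1-cycle-periodic interpolation. Shifts obey the winding-number-0
#' convention (|shift| < 1 cycle).
#'
#' @param phase node phases in cycles (wrapped to [0, 1)).
#' @param shift node phase shifts in cycles, each in (-0.5, 0.5].
#' @param kind `"dawn"` (an L function, dark-to-light steps) or `"dusk"`
#'   (a D function, light-to-dark steps).
#' @return a `step_response_function`.
#' @export
step_response_function <- function(phase, shift, kind = c("dawn", "dusk")) {
  kind <- match.arg(kind)
  if (length(phase) != length(shift)) fail("phase and shift lengths differ")
  phase <- phase %% 1
  if (any(abs(shift) >= 1))
    fail("shifts must be smaller than one cycle (winding number 0)")
  ord <- order(phase)
  phase <- phase[ord]; shift <- shift[ord]
  dup <- duplicated(phase)
  if (any(dup)) {
    off <- unique(phase[dup])
    conflicting <- off[vapply(off, function(p)
      length(unique(shift[phase == p])) > 1, logical(1))]
    if (length(conflicting))
      fail("conflicting shifts at duplicate phases: ",
           paste(signif(conflicting, 4), collapse = ", "))
    keep <- !dup
    phase <- phase[keep]; shift <- shift[keep]
  }
  structure(list(phase = phase, shift = shift, kind = kind),
            class = "step_response_function")
}

#' Assemble a step-response function from measured (phase, shift) pairs
#'
#' @param measurements data frame or list with numeric `theta` (phases,
#'   cycles) and `dtheta` (shifts, cycles).
#' @param kind `"dawn"` or `"dusk"`.
#' @return a [step_response_function()].
#' @export
assemble_step_response <- function(measurements, kind = c("dawn", "dusk")) {
  th <- measurements$theta; dth <- measurements$dtheta
  if (length(unique(th %% 1)) < 3)
    fail("need at least 3 distinct phases to assemble a step-response function")
  step_response_function(th, dth, kind = match.arg(kind))
}

#' Evaluate a step-response object
#'
#' @param object a `step_response_function` or `linear_step_params`.
#' @param theta phases in cycles (any real; evaluated mod 1).
#' @param ... unused.
#' @return phase shifts in cycles.
#' @export
predict.step_response_function <- function(object, theta, ...) {
  f <- theta %% 1
  xs <- c(object$phase - 1, object$phase, object$phase + 1)
  ys <- rep(object$shift, 3)
  stats::approx(xs, ys, xout = f, ties = "ordered")$y
}

#' @export
print.step_response_function <- function(x, ...) {
  cat(sprintf("<step_response_function [%s]: %d nodes, range [%.3f, %.3f] cycles>\n",
              x$kind, length(x$phase), min(x$shift), max(x$shift)))
  invisible(x)
}

# evaluate any supported shift-function representation
eval_shift <- function(f, theta) {
  if (is.function(f)) f(theta %% 1)
  else if (inherits(f, c("step_response_function", "linear_step_params")))
    predict(f, theta)
  else if (is.null(f)) rep(0, length(theta))
  else fail("unsupported step-response representation")
}

#' Phase shift caused by a single step perturbation
#'
#' Disentangles the instantaneous shift from the period change: the phase of
#' the control reaction and the apparent phase of the perturbed reaction
#' (fit with the post-step period) are both evaluated at the step time, and
#' their difference is the shift.
#'
#' @param control_fit `sinusoid_fit` of the unperturbed control, fit with
#'   the pre-step condition's (shared) period.
#' @param perturbed_fit `sinusoid_fit` of the stepped reaction, fit to data
#'   collected after the post-step exclusion window with the post-step
#'   condition's shared period.
#' @param t_step step time in hours.
#' @return list with `theta` (control phase at the step, raw oscillation
#'   cycles in [0,1)) and `dtheta` (shift, cycles in (-0.5, 0.5]).
#' @export
step_phase_shift <- function(control_fit, perturbed_fit, t_step) {
  if (is.null(control_fit)) fail("missing control fit")
  th_con <- raw_phase_at(control_fit, t_step)
  th_pert <- raw_phase_at(perturbed_fit, t_step)
  list(theta = th_con, dtheta = wrap_half_cycle(th_pert - th_con))
}

#' Linearize a step-response function over a circadian-time range
#'
#' Fits an unweighted regression line to the nodes falling in `ct_range`
#' (CT hours, 24 h per cycle; the range may wrap past CT 24). The stored
#' slope is the positive coefficient of \eqn{L(\theta) = -l(\theta -
#' \theta_L)}, i.e. the negated regression slope. The returned object
#' evaluates to the regression line everywhere, extended periodically with a
#' single one-cycle offset jump at the breakpoint (default: diametrically
#' opposite the midpoint of the linearization range), so that the function
#' is 1-periodic with winding number 0.
#'
#' @param F a [step_response_function()].
#' @param ct_range length-2 CT-hour range. Defaults to 18-34 CT for dawn
#'   (L) functions and 6-22 CT for dusk (D) functions, the phase windows
#'   visited during diurnal entrainment.
#' @param breakpoint optional breakpoint phase in cycles.
#' @return a `linear_step_params` object with fields `slope` (l or d),
#'   `anchor` (zero-crossing phase, cycles in [0,1)), `breakpoint`, `kind`,
#'   `ct_range`, `n_nodes`.
#' @export
linearize_step_response <- function(F, ct_range = NULL, breakpoint = NULL) {
  stopifnot(inherits(F, "step_response_function"))
  if (is.null(ct_range))
    ct_range <- if (F$kind == "dawn") c(18, 34) else c(6, 22)
  r <- ct_to_cycles(ct_range)
  if (r[2] <= r[1] || r[2] - r[1] >= 1)
    fail("ct_range must span a positive fraction of one cycle")
  u <- ((F$phase - r[1]) %% 1) + r[1]
  sel <- u <= r[2]
  if (sum(sel) < 3)
    fail("fewer than 3 nodes inside the linearization range")
  cf <- stats::lm.fit(cbind(1, u[sel]), F$shift[sel])$coefficients
  b <- cf[[2]]; a <- cf[[1]]
  slope <- -b
  anchor <- if (abs(slope) > 1e-12) (a / slope) %% 1 else NA_real_
  mid <- (r[1] + r[2]) / 2
  if (is.null(breakpoint)) breakpoint <- (mid + 0.5) %% 1
  # branch representatives differ from the regression coordinates by the
  # integer k; shift the intercept so the returned function equals the
  # regression line on the linearization range
  k <- floor(mid + 0.5)
  linear_step_params(slope, anchor, breakpoint, F$kind,
                     ct_range = ct_range, n_nodes = sum(sel),
                     c0 = a + b * k)
}

#' Construct a piecewise-linear (single-breakpoint) step-response function
#'
#' Represents \eqn{F(\theta) = -s (u(\theta) - \theta_0)} where
#' \eqn{u(\theta)} is the representative of \eqn{\theta} on the branch
#' `[breakpoint - 1, breakpoint)`. The function is exactly 1-periodic, has
#' the same slope everywhere, and jumps by `s` cycles at the breakpoint.
#'
#' @param slope positive coefficient `l` (dawn) or `d` (dusk).
#' @param anchor zero-crossing phase in cycles.
#' @param breakpoint branch-cut phase in cycles.
#' @param kind `"dawn"` or `"dusk"`.
#' @param ct_range,n_nodes optional metadata from
#'   [linearize_step_response()].
#' @param c0 optional intercept in branch coordinates, so that
#'   \eqn{F(\theta) = c_0 - s\, u(\theta)}; computed from the anchor's
#'   branch representative when absent.
#' @return a `linear_step_params` object.
#' @export
linear_step_params <- function(slope, anchor, breakpoint,
                               kind = c("dawn", "dusk"),
                               ct_range = NULL, n_nodes = NA_integer_,
                               c0 = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(slope)) fail("slope must be finite")
  if (is.null(c0)) {
    if (!is.finite(anchor)) fail("anchor must be finite when c0 is absent")
    c0 <- slope * unwrap_to_branch(anchor, breakpoint)
  }
  structure(list(slope = slope,
                 anchor = if (is.finite(anchor)) anchor %% 1 else NA_real_,
                 breakpoint = breakpoint %% 1, kind = kind,
                 ct_range = ct_range, n_nodes = n_nodes,
                 c0 = c0),
            class = "linear_step_params")
}

#' @export
predict.linear_step_params <- function(object, theta, ...) {
  u <- unwrap_to_branch(theta, object$breakpoint)
  object$c0 - object$slope * u
}

#' @export
print.linear_step_params <- function(x, ...) {
  cat(sprintf(
    "<linear_step_params [%s]: slope %.3f, anchor %.3f cyc, breakpoint %.3f cyc>\n",
    x$kind, x$slope, x$anchor, x$breakpoint))
  invisible(x)
}

#' Tabulate a linear step-response function on a phase grid
#'
#' @param params a `linear_step_params`.
#' @param n number of grid nodes.
#' @return a [step_response_function()].
#' @export
as_step_response <- function(params, n = 241) {
  th <- seq(0, 1 - 1 / n, length.out = n)
  step_response_function(th, predict(params, th), kind = params$kind)
}

#' Convert a polarization-reporter phase to a KaiC-phosphorylation phase
#'
#' The KaiC phosphorylation rhythm lags the fluorescence-polarization
#' reporter of KaiB-KaiC binding by approximately one third of a cycle
#' (2 pi/3), so step phases measured with the polarization probe are shifted
#' by -1/3 cycle to the phosphorylation convention.
#'
#' @param theta phases in cycles.
#' @return converted phases in [0, 1).
#' @export
polarization_to_phosphorylation_phase <- function(theta) (theta - 1 / 3) %% 1
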