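# Closed-form theory for linear step-response functions: the entrained
# fixed point of the dawn/dusk map, the slope m of peak time versus day
# length, the two-parameter (beta) linear-response model, and daytime
# resource-allocation bias.

#' Slope of entrained peak time versus day length
#'
#' For a phase oscillator with linear step-response functions
#' \eqn{L(\theta) = -l(\theta - \theta_L)} and
#' \eqn{D(\theta) = -d(\theta - \theta_D)}, the entrained peak time scales
#' linearly with day length, \eqn{t_{pk} = m\tau + C}, with
#' \deqn{m(l, d) = 1 - \frac{1 - (1 - l)\,\omega_D/\omega_L}{d + l - ld}.}
#' With equal frequencies in light and dark
#' (\eqn{\omega_D/\omega_L = 1}) this reduces to
#' \eqn{m = d(1 - l)/(d + l - ld)}: full dawn resetting (l = 1) gives
#' m = 0 (dawn tracking) and pure dusk resetting (l = 0, d = 1) gives
#' m = 1 (dusk tracking).
#'
#' @param l,d slopes of the linear dawn and dusk step-response functions
#'   (vectorized).
#' @param freq_ratio frequency ratio \eqn{\omega_D/\omega_L =
#'   T_{day}/T_{night}} (default 1).
#' @return slope m (dimensionless).
#' @export
slope_m <- function(l, d, freq_ratio = 1) {
  denom <- d + l - l * d
  if (any(abs(denom) < 1e-12))
    fail("degenerate parameters: d + l - l*d = 0 has no unique fixed point")
  1 - (1 - (1 - l) * freq_ratio) / denom
}

#' Linear entrainment model
#'
#' Bundles linear step-response slopes and anchors with oscillator
#' frequencies. Breakpoints default to the phases diametrically opposite
#' the anchors.
#'
#' @param l,d positive slopes of the dawn and dusk responses.
#' @param theta_L,theta_D anchor (zero-shift) phases in cycles.
#' @param params an [oscillator_params()].
#' @param breakpoint_L,breakpoint_D optional breakpoint phases in cycles.
#' @return a `linear_entrainment_model`.
#' @export
linear_entrainment_model <- function(l, d, theta_L, theta_D,
                                     params = oscillator_params(),
                                     breakpoint_L = NULL,
                                     breakpoint_D = NULL) {
  if (is.null(breakpoint_L)) breakpoint_L <- (theta_L + 0.5) %% 1
  if (is.null(breakpoint_D)) breakpoint_D <- (theta_D + 0.5) %% 1
  structure(list(l = l, d = d,
                 theta_L = theta_L %% 1, theta_D = theta_D %% 1,
                 breakpoint_L = breakpoint_L, breakpoint_D = breakpoint_D,
                 params = params),
            class = "linear_entrainment_model")
}

#' Step-response functions of a linear entrainment model
#'
#' @param model a [linear_entrainment_model()].
#' @return list with elements `L` and `D`, both [linear_step_params()].
#' @export
as_step_functions <- function(model) {
  list(L = linear_step_params(model$l, model$theta_L, model$breakpoint_L,
                              kind = "dawn"),
       D = linear_step_params(model$d, model$theta_D, model$breakpoint_D,
                              kind = "dusk"))
}

#' Entrained fixed point of the dawn/dusk map for linear step responses
#'
#' Solves the composed affine map for the dawn phase (before the dawn
#' shift): with \eqn{s = l + d - ld} and
#' \eqn{B = (1-d)(l\theta_L + \omega_L\tau) + d\theta_D + \omega_D(T-\tau)},
#' the fixed point satisfies \eqn{\theta^* = (B - k)/s} for the integer
#' winding `k`; the candidate consistent with one application of the wrapped
#' map is returned. The per-cycle contraction factor is
#' \eqn{(1-l)(1-d)}; the fixed point is stable and unique when its modulus
#' is below one.
#'
#' @param model a [linear_entrainment_model()].
#' @param T_h driving period in hours.
#' @param tau_h day length in hours.
#' @return list with `theta_dawn` (pre-shift fixed point, cycles),
#'   `theta_dawn_post` (after the dawn shift), `tpk_h`, `contraction`,
#'   `stable`, `found`.
#' @export
entrained_fixed_point <- function(model, T_h = 24, tau_h = 12) {
  l <- model$l; d <- model$d
  p <- model$params
  s <- l + d - l * d
  contraction <- (1 - l) * (1 - d)
  if (abs(contraction) >= 1 || abs(s) < 1e-12)
    return(list(theta_dawn = NA_real_, theta_dawn_post = NA_real_,
                tpk_h = NA_real_, contraction = contraction,
                stable = FALSE, found = FALSE))
  B <- (1 - d) * (l * model$theta_L + p$omega_L * tau_h) +
    d * model$theta_D + p$omega_D * (T_h - tau_h)
  sf <- as_step_functions(model)
  sched <- driving_schedule(T_h = T_h, tau_h = tau_h, n_cycles = 1)
  found <- NA_real_
  for (k in seq(floor(B - s) - 1, ceiling(B) + 1)) {
    cand <- (B - k) / s
    thc <- cand %% 1
    one <- iterate_diurnal_map(thc, p, sf$L, sf$D, sched)
    nxt <- attr(one, "final_phase_unwrapped") %% 1
    if (abs(wrap_half_cycle(nxt - thc)) < 1e-9) { found <- thc; break }
  }
  if (is.na(found))
    return(list(theta_dawn = NA_real_, theta_dawn_post = NA_real_,
                tpk_h = NA_real_, contraction = contraction,
                stable = TRUE, found = FALSE))
  post <- (found + predict(sf$L, found)) %% 1
  list(theta_dawn = found,
       theta_dawn_post = post,
       tpk_h = ((0.5 - post) %% 1) / p$omega_L,
       contraction = contraction, stable = TRUE, found = TRUE)
}

#' Two-parameter linear-response (beta) model
#'
#' In the linear regime the slopes of the phase-resetting curve, the wedge
#' response and seasonal entrainment are all set by two dimensionless
#' parameters: \eqn{\Delta t_{pk} = \hat\theta_t/(\omega_L\beta_2) +
#' \delta(1 + \beta_1/\beta_2) + C_1} for resetting by a dark pulse of
#' length \eqn{\delta}, and \eqn{t_{pk} = \tau(1 - \beta_1 - \beta_2) +
#' T\beta_1 + C_2} for entrainment.
#'
#' @param beta1,beta2 dimensionless slopes (`beta2` nonzero).
#' @param C_prc_left,C_prc_right PRC intercepts (hours) left/right of the
#'   breakpoint.
#' @param C_wedge wedge intercept (hours).
#' @param C_entrainment seasonal intercept (hours).
#' @param breakpoint PRC breakpoint phase in cycles (optional).
#' @return a `beta_model`.
#' @export
beta_model <- function(beta1, beta2, C_prc_left = 0, C_prc_right = 0,
                       C_wedge = 0, C_entrainment = 0, breakpoint = NULL) {
  if (beta2 == 0) fail("beta2 must be nonzero")
  structure(list(beta1 = beta1, beta2 = beta2,
                 C_prc_left = C_prc_left, C_prc_right = C_prc_right,
                 C_wedge = C_wedge, C_entrainment = C_entrainment,
                 breakpoint = breakpoint),
            class = "beta_model")
}

#' Predicted dark-pulse phase shift under the beta model
#'
#' @param beta a [beta_model()].
#' @param theta_t clock phase at pulse start (cycles).
#' @param delta pulse duration (hours).
#' @param omega_L light frequency (cycles/hour).
#' @param intercept which intercept applies: `"prc"` (selected by
#'   breakpoint side) or `"wedge"`.
#' @param side optional explicit PRC side (`"left"`/`"right"`), overriding
#'   the breakpoint comparison.
#' @return predicted peak-time shift in hours.
#' @export
predict_prc <- function(beta, theta_t, delta, omega_L,
                        intercept = c("prc", "wedge"), side = NULL) {
  intercept <- match.arg(intercept)
  base <- theta_t / (omega_L * beta$beta2) +
    delta * (1 + beta$beta1 / beta$beta2)
  if (intercept == "wedge") return(base + beta$C_wedge)
  if (is.null(side)) {
    if (is.null(beta$breakpoint))
      fail("PRC prediction needs a breakpoint or explicit side labels")
    if (any(theta_t == beta$breakpoint))
      warning("phase exactly at the breakpoint: side indeterminate")
    side <- ifelse(theta_t < beta$breakpoint, "left", "right")
  }
  base + ifelse(side == "left", beta$C_prc_left, beta$C_prc_right)
}

#' Predicted seasonal peak time under the beta model
#'
#' @param beta a [beta_model()].
#' @param tau day length (hours).
#' @param T_h driving period (hours, default 24).
#' @return predicted peak time in hours; the implied seasonal slope is
#'   `1 - beta1 - beta2`.
#' @export
predict_seasonal <- function(beta, tau, T_h = 24) {
  tau * (1 - beta$beta1 - beta$beta2) + T_h * beta$beta1 + beta$C_entrainment
}

#' Dawn/dusk transcription profile for allocation analysis
#'
#' Idealized 24 h sinusoidal transcription waveforms for a dawn-peaking and
#' a dusk-peaking gene class, rectified at zero, with peak times given
#' relative to dawn under the reference day length.
#'
#' @param peak_dawn_h,peak_dusk_h peak times (hours after dawn) of the dawn
#'   and dusk waveforms at the reference day length.
#' @param period waveform period in hours (default 24).
#' @return an `allocation_profile`.
#' @export
allocation_profile <- function(peak_dawn_h = 2, peak_dusk_h = 14,
                               period = 24) {
  structure(list(peak_dawn_h = peak_dawn_h, peak_dusk_h = peak_dusk_h,
                 period = period),
            class = "allocation_profile")
}

#' Bias in daytime resource allocation between dawn and dusk genes
#'
#' Under diurnal cycling the only modelled effect of day length is to shift
#' the phase of the circadian transcriptional program relative to dawn, by
#' `m * (tau - tau_ref)` hours. Each rectified waveform is integrated over
#' the daylight window `[0, tau]` and the bias is
#' \eqn{(I_{dawn} - I_{dusk}) / (I_{dawn} + I_{dusk})}.
#'
#' @param profile an [allocation_profile()].
#' @param m entrained-phase slope (dimensionless).
#' @param tau day length in hours.
#' @param tau_ref reference day length at which the stated peak times hold
#'   (default 12 h).
#' @param n integration grid size.
#' @return allocation bias in [-1, 1].
#' @export
allocation_bias <- function(profile, m, tau, tau_ref = 12, n = 4096) {
  shift <- m * (tau - tau_ref)
  tgrid <- seq(0, tau, length.out = n)
  wave <- function(peak) {
    w <- cos(2 * pi * (tgrid - (peak + shift)) / profile$period)
    pmax(w, 0)
  }
  integ <- function(y) sum((y[-1] + y[-n]) / 2) * (tau / (n - 1))
  I_dawn <- integ(wave(profile$peak_dawn_h))
  I_dusk <- integ(wave(profile$peak_dusk_h))
  if (I_dawn + I_dusk == 0) fail("zero total integral over the day window")
  (I_dawn - I_dusk) / (I_dawn + I_dusk)
}
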