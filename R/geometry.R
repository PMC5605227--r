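# Day/night limit-cycle geometry: instantaneous radial resetting between
# two circles, the step-response functions it implies, entrainment over
# (R, X) grids, and dynamical variants with finite attraction, elliptical
# orbits or modulated angular velocity.
#
# The day orbit is the unit circle at the origin; the night orbit has
# radius R and is centred at (0, X). Angles are standard polar angles in
# radians about the active orbit's centre; the rhythm peak is at
# theta = pi/2.

#' Day/night limit-cycle geometry
#'
#' @param R night-orbit radius (day orbit has radius 1).
#' @param X centre-to-centre displacement of the night orbit along +y.
#' @param attraction radial attraction rate `a` in 1/h (`Inf` for the
#'   instantaneous-jump idealization); relaxation half-time is `ln(2)/a`.
#' @param rho_day,rho_night major/minor axis ratios of the day and night
#'   orbits (1 = circular; minor axis along x, major along y).
#' @param eps amplitude of sinusoidal angular-velocity modulation
#'   (`theta-dot = omega (1 + (eps/omega) sin(omega t))`), in the same
#'   units as `omega`.
#' @param omega angular frequency in rad/h (default `2*pi/24`).
#' @param velocity_phase whether the modulation clock `t` resets at each
#'   dawn (default) or runs from simulation start.
#' @return an `orbit_geometry`.
#' @export
orbit_geometry <- function(R = 1, X = 0, attraction = Inf,
                           rho_day = 1, rho_night = 1, eps = 0,
                           omega = 2 * pi / 24,
                           velocity_phase = c("dawn", "absolute")) {
  if (R <= 0) fail("night-orbit radius must be positive")
  if (X < 0) fail("displacement X must be non-negative")
  if (rho_day < 1 || rho_night < 1) fail("axis ratios must be >= 1")
  structure(list(R = R, X = X, attraction = attraction,
                 rho_day = rho_day, rho_night = rho_night,
                 eps = eps, omega = omega,
                 velocity_phase = match.arg(velocity_phase)),
            class = "orbit_geometry")
}

# orbit descriptors
day_orbit <- function(geom) list(center = c(0, 0), radius = 1,
                                 rho = geom$rho_day)
night_orbit <- function(geom) list(center = c(0, geom$X), radius = geom$R,
                                   rho = geom$rho_night)

#' Radial jump between limit cycles
#'
#' Maps a phase on the source orbit to the phase, about the target orbit's
#' centre, of the nearest point of the target circle: the point where the
#' ray from the target centre through the source point meets the target
#' orbit.
#'
#' @param theta source phase(s) in radians.
#' @param geom an [orbit_geometry()].
#' @param from `"day"` (dusk transition) or `"night"` (dawn transition).
#' @return target phase(s) in radians, in (-pi, pi].
#' @export
radial_jump <- function(theta, geom, from = c("day", "night")) {
  from <- match.arg(from)
  src <- if (from == "day") day_orbit(geom) else night_orbit(geom)
  tgt <- if (from == "day") night_orbit(geom) else day_orbit(geom)
  px <- src$center[1] + src$radius * cos(theta)
  py <- src$center[2] + src$radius * sin(theta)
  vx <- px - tgt$center[1]
  vy <- py - tgt$center[2]
  if (any(vx^2 + vy^2 < 1e-24))
    fail("source point coincides with the target centre: jump undefined")
  atan2(vy, vx)
}

#' Step-response functions implied by the orbit geometry
#'
#' Tabulates the dusk response (day-to-night jumps) and the dawn response
#' (night-to-day jumps) on a uniform phase grid, converted to clock-phase
#' cycles (trough at phase 0, i.e. clock phase = (theta - pi/2)/(2 pi) + 1/2
#' so the peak theta = pi/2 maps to 0.5 cycles).
#'
#' @param geom an [orbit_geometry()].
#' @param n grid size (default 256).
#' @return list with `L` and `D`, both [step_response_function()].
#' @export
step_response_from_geometry <- function(geom, n = 256) {
  th <- seq(0, 2 * pi * (1 - 1 / n), length.out = n)
  to_cycles <- function(rad) ((rad - pi / 2) / (2 * pi) + 0.5) %% 1
  tab <- function(from) {
    src <- if (from == "day") day_orbit(geom) else night_orbit(geom)
    tgt <- if (from == "day") night_orbit(geom) else day_orbit(geom)
    px <- src$center[1] + src$radius * cos(th)
    py <- src$center[2] + src$radius * sin(th)
    # a source node exactly at the target centre sits on the response
    # function's genuine discontinuity; it is dropped from the tabulation
    ok <- (px - tgt$center[1])^2 + (py - tgt$center[2])^2 > 1e-18
    shift <- wrap_half_rad(radial_jump(th[ok], geom, from = from) - th[ok])
    step_response_function(to_cycles(th[ok]), shift / (2 * pi),
                           kind = if (from == "day") "dusk" else "dawn")
  }
  list(L = tab("night"), D = tab("day"))
}

#' Entrainment of the instantaneous-resetting geometric oscillator
#'
#' Simulates `n_cycles` light-dark cycles with radial jumps at dusk and
#' dawn and uniform angular velocity on each orbit. Entrainment fails if
#' the dawn phases of the final two cycles differ by more than `tol`, or if
#' simulations from the two initial phases end more than `tol` apart.
#'
#' @param geom an [orbit_geometry()].
#' @param taus day lengths in hours (default 6:18).
#' @param T_h driving period (default 24 h).
#' @param n_cycles cycles per simulation (default 30).
#' @param theta0 initial phases in radians (default `c(pi/4, 5*pi/4)`).
#' @param tol entrainment tolerance in radians (default `pi/180`).
#' @return data frame with columns `tau`, `entrained` and `phase` (final
#'   dawn phase in radians of the first initial condition).
#' @export
simulate_entrainment_instant <- function(geom, taus = 6:18, T_h = 24,
                                         n_cycles = 30,
                                         theta0 = c(pi / 4, 5 * pi / 4),
                                         tol = pi / 180) {
  omega <- geom$omega
  run <- function(tau, th0) {
    th <- th0
    last_two <- c(NA_real_, NA_real_)
    for (k in seq_len(n_cycles)) {
      th <- th + omega * tau                      # day
      th <- radial_jump(th, geom, from = "day")   # dusk jump
      th <- th + omega * (T_h - tau)              # night
      th <- radial_jump(th, geom, from = "night") # dawn jump
      last_two <- c(last_two[2], th)
    }
    last_two
  }
  out <- data.frame(tau = taus, entrained = NA, phase = NA_real_)
  for (i in seq_along(taus)) {
    a <- run(taus[i], theta0[1])
    b <- run(taus[i], theta0[2])
    ok <- abs(wrap_half_rad(a[2] - a[1])) <= tol &&
      abs(wrap_half_rad(b[2] - b[1])) <= tol &&
      abs(wrap_half_rad(a[2] - b[2])) <= tol
    out$entrained[i] <- ok
    out$phase[i] <- a[2] %% (2 * pi)
  }
  out
}

# unwrap a sequence of angles (radians) so successive differences lie in
# (-pi, pi]
unwrap_rad <- function(x) {
  if (length(x) < 2) return(x)
  cumsum(c(x[1], wrap_half_rad(diff(x))))
}

#' Slope of entrained phase versus day length over an (R, X) grid
#'
#' For each geometry on the grid, simulates entrainment across the
#' day-length range, converts the entrained dawn phases to hours
#' (time to reach the peak phase `pi/2` at angular velocity `omega`), and
#' fits a line against day length. Cells are masked (`NA`) where any day
#' length fails the entrainment criteria or where the mean absolute fit
#' residual exceeds 10% of the phase excursion (plus, for dynamical
#' variants, 0.5 h).
#'
#' @param R_grid,X_grid geometry grids.
#' @param taus day lengths in hours.
#' @param variant `"instant"` (radial-jump map) or `"dynamic"`
#'   (finite-attraction integration; see [simulate_entrainment_dynamic()]).
#' @param ... further arguments passed to the per-geometry simulator
#'   (e.g. `attraction`, `dt`, `n_cycles`).
#' @return list with matrices `m` (slope; rows = `R_grid`, columns =
#'   `X_grid`) and `entrained` (logical mask).
#' @export
slope_over_grid <- function(R_grid, X_grid, taus = 6:18,
                            variant = c("instant", "dynamic"), ...) {
  variant <- match.arg(variant)
  m <- matrix(NA_real_, length(R_grid), length(X_grid),
              dimnames = list(signif(R_grid, 3), signif(X_grid, 3)))
  ok <- matrix(FALSE, length(R_grid), length(X_grid))
  for (i in seq_along(R_grid)) for (j in seq_along(X_grid)) {
    fit <- slope_for_geometry(R_grid[i], X_grid[j], taus, variant, ...)
    m[i, j] <- fit$m
    ok[i, j] <- fit$entrained
  }
  list(m = m, entrained = ok)
}

slope_for_geometry <- function(R, X, taus, variant, attraction = 1,
                               dt = 0.01, n_cycles = NULL, omega = 2 * pi / 24,
                               ...) {
  if (variant == "instant") {
    geom <- orbit_geometry(R = R, X = X, omega = omega)
    sim <- simulate_entrainment_instant(geom, taus = taus,
                                        n_cycles = n_cycles %||% 30)
    if (!all(sim$entrained)) return(list(m = NA_real_, entrained = FALSE))
    y <- unwrap_rad(sim$phase)
    y_h <- ((pi / 2 - y) / omega) # hours until theta = pi/2
    extra_tol <- 0
  } else {
    geom <- orbit_geometry(R = R, X = X, attraction = attraction,
                           omega = omega, ...)
    sims <- lapply(taus, function(tau)
      simulate_entrainment_dynamic(geom, tau = tau, dt = dt,
                                   n_cycles = n_cycles %||% 10))
    if (!all(vapply(sims, `[[`, logical(1), "entrained")))
      return(list(m = NA_real_, entrained = FALSE))
    y_h <- vapply(sims, `[[`, numeric(1), "tpk_h")
    # peak times may wrap by a full period across the day-length range
    y_h <- unwrap_rad(y_h * omega) / omega
    extra_tol <- 0.5
  }
  fit <- stats::lm(y_h ~ taus)
  mfe <- mean(abs(stats::resid(fit)))
  nonlinear <- if (extra_tol > 0)
    mfe > extra_tol && mfe > 0.1 * diff(range(y_h))
  else mfe > 0.1 * diff(range(y_h))
  if (nonlinear) return(list(m = NA_real_, entrained = FALSE))
  list(m = unname(stats::coef(fit)[2]), entrained = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# radius of an ellipse (minor axis R along x, major rho*R along y) at polar
# angle theta about its centre
ellipse_radius <- function(theta, R, rho) {
  1 / sqrt(cos(theta)^2 / R^2 + sin(theta)^2 / (rho^2 * R^2))
}

# signed distance from polar point (r, theta) to the ellipse, via bounded
# 1-D minimization over the ellipse parameter angle
ellipse_signed_distance <- function(r, theta, R, rho) {
  px <- r * cos(theta); py <- r * sin(theta)
  dist2 <- function(u) (R * cos(u) - px)^2 + (rho * R * sin(u) - py)^2
  opt <- stats::optimize(dist2, interval = c(theta - pi / 2, theta + pi / 2),
                         tol = 1e-10)
  sign(r - ellipse_radius(theta, R, rho)) * sqrt(opt$objective)
}

# time derivative of the ellipse radius along the orbit at angle theta,
# for angular velocity thetadot
ellipse_radius_dot <- function(theta, R, rho, thetadot) {
  q <- cos(theta)^2 / R^2 + sin(theta)^2 / (rho^2 * R^2)
  -0.5 * q^(-1.5) *
    (-2 * thetadot * cos(theta) * sin(theta) / R^2 +
       2 * thetadot * cos(theta) * sin(theta) / (rho^2 * R^2))
}

#' Integrate relaxation dynamics toward a limit cycle
#'
#' Fixed-step fourth-order Runge-Kutta integration of the polar dynamics
#' about the active orbit's centre: `theta-dot = omega (1 + (eps/omega)
#' sin(omega t))` and `r-dot = -a (r - R_orb)` for circular orbits, or
#' `r-dot = -a d_ellipse + r-dot_ellipse(theta)` for elliptical orbits.
#'
#' @param state numeric `c(theta, r)` relative to the orbit centre.
#' @param geom an [orbit_geometry()].
#' @param orbit `"day"` or `"night"`.
#' @param duration integration span in hours.
#' @param dt step size in hours (default 0.01).
#' @param t0 modulation-clock time at the start (hours).
#' @return matrix with columns `time_h`, `theta`, `r` (rows are steps,
#'   including the initial state).
#' @export
integrate_relaxation <- function(state, geom, orbit = c("day", "night"),
                                 duration, dt = 0.01, t0 = 0) {
  orbit <- match.arg(orbit)
  ob <- if (orbit == "day") day_orbit(geom) else night_orbit(geom)
  a <- geom$attraction
  omega <- geom$omega
  eps <- geom$eps
  elliptical <- ob$rho > 1
  deriv <- function(t, th, r) {
    thdot <- omega * (1 + (eps / omega) * sin(omega * t))
    rdot <- if (elliptical) {
      -a * ellipse_signed_distance(r, th, ob$radius, ob$rho) +
        ellipse_radius_dot(th, ob$radius, ob$rho, thdot)
    } else -a * (r - ob$radius)
    c(thdot, rdot)
  }
  n <- round(duration / dt)
  if (abs(n * dt - duration) > 1e-9)
    fail("duration must be a multiple of dt")
  out <- matrix(NA_real_, n + 1, 3,
                dimnames = list(NULL, c("time_h", "theta", "r")))
  th <- state[1]; r <- state[2]
  out[1, ] <- c(t0, th, r)
  for (k in seq_len(n)) {
    t <- t0 + (k - 1) * dt
    k1 <- deriv(t, th, r)
    k2 <- deriv(t + dt / 2, th + dt / 2 * k1[1], r + dt / 2 * k1[2])
    k3 <- deriv(t + dt / 2, th + dt / 2 * k2[1], r + dt / 2 * k2[2])
    k4 <- deriv(t + dt, th + dt * k3[1], r + dt * k3[2])
    th <- th + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    r <- r + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    out[k + 1, ] <- c(t + dt, th, r)
  }
  out
}

# convert polar coordinates about one orbit centre to polar about another
repolarize <- function(th, r, from_center, to_center) {
  px <- from_center[1] + r * cos(th)
  py <- from_center[2] + r * sin(th)
  c(theta = atan2(py - to_center[2], px - to_center[1]),
    r = sqrt((px - to_center[1])^2 + (py - to_center[2])^2))
}

#' Entrainment of the dynamical (finite-attraction) geometric oscillator
#'
#' Integrates the relaxation dynamics through `n_cycles` light-dark cycles;
#' at dusk and dawn the Cartesian state is re-expressed in polar
#' coordinates about the newly active orbit's centre (no jump). After the
#' final dawn the oscillator relaxes back to the day orbit and the peak
#' time is the additional time needed to reach `theta = pi/2`
#' (see [peak_time_dynamic()]). Entrainment is judged on the dawn phases of
#' the last two cycles and across the two initial phases, as in the
#' instantaneous variant.
#'
#' @param geom an [orbit_geometry()] with finite `attraction`.
#' @param tau day length in hours.
#' @param T_h driving period (default 24 h).
#' @param n_cycles number of cycles (default 10).
#' @param theta0 initial phases in radians (default `c(0, pi)`).
#' @param dt integration step (default 0.01 h).
#' @param tol entrainment tolerance in radians (default `pi/180`).
#' @return list with `entrained`, `tpk_h` (from the first initial phase)
#'   and `dawn_phase` (radians).
#' @export
simulate_entrainment_dynamic <- function(geom, tau, T_h = 24, n_cycles = 10,
                                         theta0 = c(0, pi), dt = 0.01,
                                         tol = pi / 180) {
  if (!is.finite(geom$attraction))
    fail("dynamical variant needs a finite attraction rate")
  dayo <- day_orbit(geom); nighto <- night_orbit(geom)
  run <- function(th0) {
    th <- th0
    r <- if (dayo$rho > 1) ellipse_radius(th0, 1, dayo$rho) else 1
    dawns <- numeric(n_cycles)
    for (k in seq_len(n_cycles)) {
      t0 <- if (geom$velocity_phase == "dawn") 0 else (k - 1) * T_h
      seg <- integrate_relaxation(c(th, r), geom, "day", tau, dt, t0 = t0)
      st <- repolarize(seg[nrow(seg), "theta"], seg[nrow(seg), "r"],
                       dayo$center, nighto$center)
      seg <- integrate_relaxation(st, geom, "night", T_h - tau, dt,
                                  t0 = t0 + tau)
      st <- repolarize(seg[nrow(seg), "theta"], seg[nrow(seg), "r"],
                       nighto$center, dayo$center)
      th <- st[1]; r <- st[2]
      dawns[k] <- th
    }
    list(dawns = dawns, theta = th, r = r)
  }
  s1 <- run(theta0[1])
  s2 <- run(theta0[2])
  ok <- abs(wrap_half_rad(s1$dawns[n_cycles] - s1$dawns[n_cycles - 1])) <= tol &&
    abs(wrap_half_rad(s2$dawns[n_cycles] - s2$dawns[n_cycles - 1])) <= tol &&
    abs(wrap_half_rad(s1$theta - s2$theta)) <= tol
  tpk <- peak_time_dynamic(s1$theta, s1$r, geom, dt = dt)
  list(entrained = ok, tpk_h = tpk, dawn_phase = s1$theta %% (2 * pi))
}

#' Peak time after relaxation to the day orbit
#'
#' From a state at the final dawn, integrates the day dynamics until the
#' radius is within 1% of the day orbit, then reports the additional time
#' needed to first cross phase `theta = pi/2` (mod 2 pi).
#'
#' @param theta,r polar state about the day-orbit centre at the final dawn.
#' @param geom an [orbit_geometry()].
#' @param dt integration step (default 0.01 h).
#' @param max_h give up after this many hours (default 96).
#' @return peak time in hours (time from orbit return to the peak crossing).
#' @export
peak_time_dynamic <- function(theta, r, geom, dt = 0.01, max_h = 96) {
  traj <- integrate_relaxation(c(theta, r), geom, "day", max_h, dt)
  rel_tol <- 0.01 * day_orbit(geom)$radius
  i0 <- which(abs(traj[, "r"] - day_orbit(geom)$radius) <= rel_tol)[1]
  if (is.na(i0)) fail("oscillator did not relax to the day orbit")
  th <- traj[i0:nrow(traj), "theta"]
  t <- traj[i0:nrow(traj), "time_h"]
  target <- th[1] + ((pi / 2 - th[1]) %% (2 * pi))
  i <- which(th >= target)[1]
  if (is.na(i)) fail("no peak crossing within the integration span")
  if (i == 1) return(0)
  tc <- t[i - 1] + (target - th[i - 1]) / (th[i] - th[i - 1]) * (t[i] - t[i - 1])
  tc - t[1]
}
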