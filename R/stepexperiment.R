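# Estimation of L and D step-response functions from step-perturbation
# experiments, and non-parametric bootstrap propagation of their
# uncertainty.

#' Bundle step-perturbation trajectories with their metadata
#'
#' @param trajectories list of [clock_trajectory()] objects.
#' @param meta data frame with one row per trajectory and columns
#'   `series_id`, `role` (`"control"` or `"step"`), `condition` (buffer the
#'   reaction is in while fit: `"day"` or `"night"`), `direction`
#'   (`"up"` = night-to-day, `"down"` = day-to-night, `NA` for controls)
#'   and `step_time_h` (`NA` for controls).
#' @param exclusion_window_h hours of data discarded after each step to
#'   avoid transients (default 16).
#' @return a `step_experiment_set`.
#' @export
step_experiment_set <- function(trajectories, meta, exclusion_window_h = 16) {
  meta <- as.data.frame(meta)
  need <- c("series_id", "role", "condition", "direction", "step_time_h")
  if (!all(need %in% names(meta)))
    fail("meta must have columns: ", paste(need, collapse = ", "))
  if (length(trajectories) != nrow(meta))
    fail("one meta row per trajectory required")
  if (exclusion_window_h < 0) fail("exclusion window must be >= 0")
  is_step <- meta$role == "step"
  if (any(is_step & !is.finite(meta$step_time_h)))
    fail("every stepped trajectory needs exactly one step time")
  structure(list(trajectories = trajectories, meta = meta,
                 exclusion_window_h = exclusion_window_h),
            class = "step_experiment_set")
}

#' @export
print.step_experiment_set <- function(x, ...) {
  cat(sprintf("<step_experiment_set: %d trajectories (%d controls, %d up, %d down)>\n",
              nrow(x$meta), sum(x$meta$role == "control"),
              sum(x$meta$direction == "up", na.rm = TRUE),
              sum(x$meta$direction == "down", na.rm = TRUE)))
  invisible(x)
}

# trim a stepped trajectory to >= step + exclusion window, then normalize
prepare_step_trajectory <- function(traj, step_time, exclusion) {
  tr <- if (is.finite(step_time))
    window_trajectory(traj, from = step_time + exclusion) else traj
  normalize_trajectory(tr, discard_after_lights_on = 0)
}

#' Estimate L and D step-response functions from a step experiment set
#'
#' Trajectories are trimmed to at least `exclusion_window_h` hours after
#' their step, normalized, and fit with shared periods per buffer
#' condition (day-buffer fits share `T_day`; night-buffer fits share
#' `T_night`). For each stepped reaction the phase shift is the difference
#' between the perturbed reaction's apparent phase and the matching
#' control's phase, both evaluated at the step time; the control phase
#' locates the measurement on the phase axis. Node phases are converted to
#' the clock-phase convention (trough at 0).
#'
#' @param set a [step_experiment_set()].
#' @param period_bounds bounds for the shared-period fits (default
#'   `c(20, 30)` hours).
#' @param ct_range_L,ct_range_D linearization ranges in CT hours.
#' @param phase_lag_cycles constant subtracted from node phases before
#'   assembly, e.g. `1/3` for the polarization-to-phosphorylation
#'   conversion (default 0).
#' @return list with `L`, `D` ([step_response_function()]), `L_lin`,
#'   `D_lin` ([linear_step_params()]), `T_day`, `T_night`, and the node
#'   tables `nodes_L`, `nodes_D`.
#' @export
estimate_step_response <- function(set, period_bounds = c(20, 30),
                                   ct_range_L = c(18, 34),
                                   ct_range_D = c(6, 22),
                                   phase_lag_cycles = 0) {
  meta <- set$meta
  prep <- lapply(seq_len(nrow(meta)), function(i)
    prepare_step_trajectory(set$trajectories[[i]], meta$step_time_h[i],
                            set$exclusion_window_h))
  names(prep) <- meta$series_id
  for (cond in c("day", "night"))
    if (!any(meta$role == "control" & meta$condition == cond))
      fail("missing ", cond, "-buffer control reaction")
  day_fit <- fit_sinusoids_shared_period(prep[meta$condition == "day"],
                                         period_bounds)
  night_fit <- fit_sinusoids_shared_period(prep[meta$condition == "night"],
                                           period_bounds)
  fits <- c(day_fit$fits, night_fit$fits)
  ctrl_day <- fits[[meta$series_id[meta$role == "control" &
                                     meta$condition == "day"][1]]]
  ctrl_night <- fits[[meta$series_id[meta$role == "control" &
                                       meta$condition == "night"][1]]]
  shift_nodes <- function(direction) {
    rows <- which(meta$role == "step" & meta$direction == direction)
    ctrl <- if (direction == "down") ctrl_day else ctrl_night
    do.call(rbind, lapply(rows, function(i) {
      s <- step_phase_shift(ctrl, fits[[meta$series_id[i]]],
                            meta$step_time_h[i])
      data.frame(series_id = meta$series_id[i],
                 theta = (s$theta + 0.25 - phase_lag_cycles) %% 1,
                 dtheta = s$dtheta)
    }))
  }
  nodes_D <- shift_nodes("down")
  nodes_L <- shift_nodes("up")
  L <- assemble_step_response(nodes_L, kind = "dawn")
  D <- assemble_step_response(nodes_D, kind = "dusk")
  list(L = L, D = D,
       L_lin = linearize_step_response(L, ct_range_L),
       D_lin = linearize_step_response(D, ct_range_D),
       T_day = day_fit$period, T_night = night_fit$period,
       nodes_L = nodes_L, nodes_D = nodes_D)
}

#' Bootstrap the master step-response dataset
#'
#' Resamples whole trajectories with replacement from the entire master
#' dataset (controls and steps pooled) and re-runs the full estimation for
#' each resample, so that correlated uncertainty in the shared periods and
#' control phases propagates into the L/D functions and their linearized
#' slopes. Resamples lacking a control in either buffer condition or
#' having fewer than 3 distinct step phases per direction are redrawn (the
#' count of redraws is recorded).
#'
#' @param set a [step_experiment_set()].
#' @param n number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param ... passed on to [estimate_step_response()].
#' @return a `bootstrap_ensemble`: list with `members` (list of
#'   [estimate_step_response()] results), `n`, `seed`, `n_redrawn`.
#' @export
bootstrap_master_dataset <- function(set, n = 1000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  meta <- set$meta
  N <- nrow(meta)
  valid <- function(idx) {
    m <- meta[idx, ]
    all(vapply(c("day", "night"), function(cond)
      any(m$role == "control" & m$condition == cond), logical(1))) &&
      length(unique(m$step_time_h[m$role == "step" &
                                    m$direction == "down"])) >= 3 &&
      length(unique(m$step_time_h[m$role == "step" &
                                    m$direction == "up"])) >= 3
  }
  members <- vector("list", n)
  n_redrawn <- 0L
  for (b in seq_len(n)) {
    repeat {
      idx <- sample.int(N, N, replace = TRUE)
      if (!valid(idx)) { n_redrawn <- n_redrawn + 1L; next }
      # duplicated series ids are disambiguated so shared fits treat each
      # resampled trajectory as its own reaction
      trajs <- set$trajectories[idx]
      m <- meta[idx, ]
      m$series_id <- make.unique(m$series_id)
      for (i in seq_along(trajs))
        attr(trajs[[i]], "series_id") <- m$series_id[i]
      sub <- step_experiment_set(trajs, m, set$exclusion_window_h)
      est <- tryCatch(estimate_step_response(sub, ...),
                      error = function(e) NULL)
      if (!is.null(est)) { members[[b]] <- est; break }
      n_redrawn <- n_redrawn + 1L # e.g. too few nodes in a linear region
    }
  }
  structure(list(members = members, n = n, seed = seed,
                 n_redrawn = n_redrawn),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("<bootstrap_ensemble: %d members, %d redraws>\n",
              x$n, x$n_redrawn))
  invisible(x)
}

#' Summarize a bootstrap ensemble at a phase grid
#'
#' @param ensemble a `bootstrap_ensemble`.
#' @param theta phase grid in cycles.
#' @param which `"L"` or `"D"`.
#' @return data frame with `theta`, `mean`, `sd` of the ensemble shift.
#' @export
summarize_ensemble <- function(ensemble, theta = seq(0, 0.99, by = 0.01),
                               which = c("L", "D")) {
  which <- match.arg(which)
  vals <- vapply(ensemble$members, function(m) predict(m[[which]], theta),
                 numeric(length(theta)))
  data.frame(theta = theta,
             mean = rowMeans(vals),
             sd = apply(vals, 1, stats::sd))
}

#' Bootstrap distribution of a linearized step-response slope
#'
#' Resamples the nodes inside the linearization region with replacement,
#' keeping only resamples with at least three unique points, and records
#' the (negated) regression slope of each.
#'
#' @param F a [step_response_function()].
#' @param ct_range linearization range in CT hours (defaults as in
#'   [linearize_step_response()]).
#' @param n number of retained resamples (default 500).
#' @param seed RNG seed.
#' @return list with `slopes` (vector of length `n`), `mean`, `sd`.
#' @export
bootstrap_slopes <- function(F, ct_range = NULL, n = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ct_range))
    ct_range <- if (F$kind == "dawn") c(18, 34) else c(6, 22)
  r <- ct_to_cycles(ct_range)
  u <- ((F$phase - r[1]) %% 1) + r[1]
  sel <- u <= r[2]
  if (length(unique(u[sel])) < 3)
    fail("fewer than 3 unique nodes in the linearization region")
  uu <- u[sel]; ss <- F$shift[sel]
  slopes <- numeric(n)
  got <- 0L
  while (got < n) {
    idx <- sample.int(length(uu), length(uu), replace = TRUE)
    if (length(unique(uu[idx])) < 3) next
    got <- got + 1L
    cf <- stats::lm.fit(cbind(1, uu[idx]), ss[idx])$coefficients
    slopes[got] <- -cf[[2]]
  }
  list(slopes = slopes, mean = mean(slopes), sd = stats::sd(slopes))
}
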