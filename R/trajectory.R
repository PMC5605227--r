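# Rhythm time series: construction, masking and normalization.

#' Construct a rhythm trajectory
#'
#' A trajectory is one recorded (or synthetic) rhythm: signal values at
#' strictly increasing times, each sample annotated with a light/dark flag.
#'
#' @param time_h sampling times in hours since experiment start,
#'   strictly increasing.
#' @param value signal values (arbitrary units), same length as `time_h`.
#' @param light per-sample light annotation, 1 = lights on, 0 = dark;
#'   recycled if scalar.
#' @param series_id character label for the series.
#' @param schedule optional [driving_schedule()] the series was recorded
#'   under.
#' @return an object of class `clock_trajectory`: a data frame with columns
#'   `time_h`, `value`, `light` and `retained`, plus attributes `series_id`,
#'   `schedule` and `normalized`.
#' @export
clock_trajectory <- function(time_h, value, light = 1, series_id = "series",
                             schedule = NULL) {
  time_h <- as.numeric(time_h)
  value <- as.numeric(value)
  if (length(time_h) != length(value))
    fail("time_h and value must have the same length")
  if (any(diff(time_h) <= 0))
    fail("times must be strictly increasing in series '", series_id, "'")
  light <- rep_len(as.numeric(light), length(time_h))
  if (!all(light %in% c(0, 1)))
    fail("light flags must be 0 or 1 in series '", series_id, "'")
  out <- data.frame(time_h = time_h, value = value, light = light,
                    retained = light == 1)
  structure(out,
            series_id = series_id,
            schedule = schedule,
            normalized = FALSE,
            class = c("clock_trajectory", "data.frame"))
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat(sprintf("<clock_trajectory '%s': %d samples, %.1f-%.1f h, %d retained%s>\n",
              attr(x, "series_id"), nrow(x), min(x$time_h), max(x$time_h),
              sum(x$retained),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  invisible(x)
}

# indices of dark -> light transitions (first sample of each light stretch
# that follows a dark sample)
dawn_times <- function(traj) {
  lt <- traj$light
  idx <- which(lt == 1 & c(0, lt[-length(lt)]) == 0)
  idx <- idx[idx > 1] # a series starting in the light has no dawn at t[1]
  traj$time_h[idx]
}

#' Normalize a trajectory and mask dark/masking-window samples
#'
#' Dark samples and samples within `discard_after_lights_on` hours after any
#' dark-to-light transition are flagged excluded (the bacterial luciferase
#' reporter shows clock-independent transients after lights-on). Retained
#' samples are scaled to zero mean and unit standard deviation; excluded
#' samples are set to `NA`. The operation is idempotent.
#'
#' @param traj a [clock_trajectory()].
#' @param discard_after_lights_on masking window in hours (default 2.5).
#' @return the normalized `clock_trajectory`.
#' @export
normalize_trajectory <- function(traj, discard_after_lights_on = 2.5) {
  stopifnot(inherits(traj, "clock_trajectory"))
  dawns <- dawn_times(traj)
  masked <- rep(FALSE, nrow(traj))
  for (td in dawns)
    masked <- masked | (traj$time_h >= td &
                          traj$time_h < td + discard_after_lights_on)
  retained <- traj$light == 1 & !masked
  id <- attr(traj, "series_id")
  if (sum(retained) < 4)
    fail("series '", id, "': fewer than 4 samples retained after masking")
  v <- traj$value[retained]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    fail("series '", id, "': zero variance after masking, cannot normalize")
  traj$value[retained] <- (v - mean(v)) / s
  traj$value[!retained] <- NA_real_
  traj$retained <- retained
  attr(traj, "normalized") <- TRUE
  traj
}

#' Restrict a trajectory to a time window
#'
#' @param traj a [clock_trajectory()].
#' @param from,to window bounds in hours (inclusive).
#' @return the windowed `clock_trajectory`.
#' @export
window_trajectory <- function(traj, from = -Inf, to = Inf) {
  keep <- traj$time_h >= from & traj$time_h <= to
  out <- traj[keep, , drop = FALSE]
  attributes(out)[c("series_id", "schedule", "normalized")] <-
    attributes(traj)[c("series_id", "schedule", "normalized")]
  class(out) <- class(traj)
  out
}

# retained (time, value) pairs of a trajectory, as a list
retained_xy <- function(traj) {
  if (inherits(traj, "clock_trajectory")) {
    keep <- traj$retained & is.finite(traj$value)
    list(x = traj$time_h[keep], y = traj$value[keep],
         id = attr(traj, "series_id"))
  } else {
    list(x = as.numeric(traj$time_h), y = as.numeric(traj$value),
         id = "series")
  }
}
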