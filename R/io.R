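# Plain-text interchange formats: long-format time-series CSV, step-function
# CSV, observation CSV and schedule JSON. All numeric fields round-trip at
# full double precision (15 significant digits).

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Read a long-format time-series CSV
#'
#' Expected columns: `time_h`, `series_id`, `value`, `light` (0/1). Each
#' series becomes one [clock_trajectory()].
#'
#' @param path file path.
#' @return named list of `clock_trajectory` objects.
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "series_id", "value", "light")
  if (!all(need %in% names(df)))
    fail(path, ": missing columns ", paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!(df$light %in% c(0, 1)))
  if (length(bad))
    fail(path, ": invalid light flag at data line ", bad[1] + 1)
  split_df <- split(df, df$series_id)
  out <- lapply(split_df, function(s)
    clock_trajectory(s$time_h, s$value, s$light, series_id = s$series_id[1]))
  out[unique(df$series_id)]
}

#' Write trajectories to a long-format CSV
#'
#' @param trajs list of [clock_trajectory()] objects (or a single one).
#' @param path output path.
#' @export
write_timeseries_csv <- function(trajs, path) {
  if (inherits(trajs, "clock_trajectory")) trajs <- list(trajs)
  rows <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(time_h = fmt_num(tr$time_h),
               series_id = attr(tr, "series_id"),
               value = fmt_num(tr$value), light = tr$light)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a step-response function CSV
#'
#' Expected columns: `phase_cycles`, `shift_cycles`, `kind`
#' (`dawn`/`dusk`); one function per kind.
#'
#' @param path file path.
#' @return list with elements `L` and/or `D`
#'   ([step_response_function()]s).
#' @export
read_stepfun_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase_cycles", "shift_cycles", "kind")
  if (!all(need %in% names(df)))
    fail(path, ": missing columns ", paste(setdiff(need, names(df)), collapse = ", "))
  out <- list()
  if (any(df$kind == "dawn"))
    out$L <- step_response_function(df$phase_cycles[df$kind == "dawn"],
                                    df$shift_cycles[df$kind == "dawn"], "dawn")
  if (any(df$kind == "dusk"))
    out$D <- step_response_function(df$phase_cycles[df$kind == "dusk"],
                                    df$shift_cycles[df$kind == "dusk"], "dusk")
  out
}

#' Write step-response functions to CSV
#'
#' @param funs list of [step_response_function()] objects.
#' @param path output path.
#' @export
write_stepfun_csv <- function(funs, path) {
  if (inherits(funs, "step_response_function")) funs <- list(funs)
  rows <- do.call(rbind, lapply(funs, function(f)
    data.frame(phase_cycles = fmt_num(f$phase),
               shift_cycles = fmt_num(f$shift),
               kind = f$kind)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read observation sets for the global fit from CSV
#'
#' Expected columns: `kind`, `response`, `sem`, and the predictors
#' `theta_t`, `delta`, `tau`, `T_h`, `side`, `omega_L` (empty where not
#' applicable).
#'
#' @param path file path.
#' @return list of [observation_set()] objects, one per kind present.
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$kind), function(s) {
    observation_set(s$kind[1], s$response, s$sem,
                    theta_t = if (all(is.na(s$theta_t))) NULL else s$theta_t,
                    delta = if (all(is.na(s$delta))) NULL else s$delta,
                    tau = if (all(is.na(s$tau))) NULL else s$tau,
                    T_h = if (all(is.na(s$T_h))) NULL else s$T_h,
                    side = if (all(is.na(s$side)) || all(s$side == ""))
                      NULL else s$side,
                    omega_L = if (all(is.na(s$omega_L))) NULL
                      else s$omega_L[1])
  })
}

#' Write sinusoid fits to a CSV table
#'
#' One row per series with columns `series_id, A, T_h, phi_rad, b, C,
#' sq_err, n`.
#'
#' @param fits list of `sinusoid_fit` objects.
#' @param path output path.
#' @export
write_fits_csv <- function(fits, path) {
  rows <- do.call(rbind, lapply(fits, function(f)
    data.frame(series_id = f$series_id, A = fmt_num(f$amplitude),
               T_h = fmt_num(f$period), phi_rad = fmt_num(f$phase),
               b = fmt_num(f$trend), C = fmt_num(f$baseline),
               sq_err = fmt_num(f$squared_error), n = f$n_points)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a driving schedule from JSON
#'
#' Schema: `{T_h, tau_h, n_cycles, release_time_h, pulses:[{start_h,
#' duration_h}]}` (release and pulses optional).
#'
#' @param path file path.
#' @return a [driving_schedule()].
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  driving_schedule(T_h = x$T_h, tau_h = x$tau_h,
                   n_cycles = x$n_cycles %||% 10,
                   release_time_h = x$release_time_h,
                   pulses = x$pulses)
}

#' Write a driving schedule to JSON
#'
#' @param schedule a [driving_schedule()].
#' @param path output path.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(schedule[!vapply(schedule, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
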