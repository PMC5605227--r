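# Nonparametric comparison of driven and free-running waveforms.

#' Kendall similarity between entrained days and the post-release rhythm
#'
#' For each entraining day, computes Kendall's rank correlation (the
#' tie-adjusted tau-b, as implemented by [stats::cor()]) between the
#' retained daytime samples of that day and the samples recorded at the same
#' times after the release into constant conditions. High correlation from
#' the second cycle onward indicates that the driven rhythm is a fragment of
#' the free-running waveform, i.e. stable entrainment.
#'
#' @param traj a normalized [clock_trajectory()] covering the entraining
#'   cycles and the post-release window.
#' @param schedule a [driving_schedule()] with `release_time_h` set.
#' @return data frame with columns `cycle` and `tau`.
#' @export
kendall_entrainment_similarity <- function(traj, schedule) {
  stopifnot(inherits(traj, "clock_trajectory"))
  if (is.null(schedule$release_time_h))
    fail("schedule must define release_time_h")
  rel <- schedule$release_time_h
  n_cycles <- schedule$n_cycles
  T <- schedule$T_h
  keep <- traj$retained & is.finite(traj$value)
  t_all <- traj$time_h
  out <- data.frame(cycle = seq_len(n_cycles), tau = NA_real_)
  for (k in seq_len(n_cycles)) {
    dawn <- (k - 1) * T
    in_day <- which(keep & t_all >= dawn & t_all < dawn + schedule$tau_h)
    in_rel <- which(keep & t_all >= rel & t_all < rel + schedule$tau_h)
    off_day <- round(t_all[in_day] - dawn, 6)
    off_rel <- round(t_all[in_rel] - rel, 6)
    # samples are paired by exactly matching times-after-dawn; offsets that
    # exist in only one window (e.g. masked at one dawn) are dropped, and
    # nothing is interpolated
    common <- intersect(off_day, off_rel)
    if (length(common) < 3)
      fail("cycle ", k, ": sampling grids of the entraining day and the ",
           "post-release window do not match; no interpolation is performed")
    out$tau[k] <- stats::cor(
      traj$value[in_day[match(common, off_day)]],
      traj$value[in_rel[match(common, off_rel)]],
      method = "kendall")
  }
  out
}
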