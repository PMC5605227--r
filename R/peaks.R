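# Local parabolic regression around rhythm peaks, and outlier rejection
# of poorly fitting series.

# local maxima of the 3-sample moving median, with a minimum separation
find_peak_candidates <- function(x, y, min_separation) {
  n <- length(y)
  if (n < 3) return(integer(0))
  med <- y
  med[2:(n - 1)] <- vapply(2:(n - 1), function(i)
    stats::median(y[(i - 1):(i + 1)]), numeric(1))
  is_max <- c(FALSE, med[2:(n - 1)] >= med[1:(n - 2)] &
                     med[2:(n - 1)] >= med[3:n], FALSE)
  cand <- which(is_max & med >= stats::median(y)) # troughs are not peaks
  cand <- cand[order(-y[cand])]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || all(abs(x[i] - x[keep]) >= min_separation))
      keep <- c(keep, i)
  sort(keep)
}

#' Estimate peak times by local parabolic regression
#'
#' Parabolas are fit by least squares to fixed-width windows (default 6 h)
#' around candidate peaks of the retained signal; each peak time is the
#' parabola vertex. Candidate peaks are local maxima of a 3-sample moving
#' median separated by at least `min_separation` hours. Vertices falling
#' outside their window, or windows fit by an upward-opening parabola, are
#' rejected with a warning.
#'
#' @param traj a [clock_trajectory()] or data frame with `time_h`, `value`.
#' @param window full window width in hours (default 6).
#' @param min_separation minimum spacing between candidate peaks in hours
#'   (default 12, half a circadian cycle).
#' @return a `peak_estimate` object: list with `peak_times` (hours,
#'   increasing), `period_estimate` (mean successive spacing, `NA` if fewer
#'   than two peaks), `windows` (matrix of window bounds), `n_rejected`.
#' @export
fit_peaks_parabolic <- function(traj, window = 6, min_separation = 12) {
  xy <- retained_xy(traj)
  x <- xy$x; y <- xy$y
  if (length(x) < 3 || diff(range(x)) < window)
    fail("series '", xy$id, "': trajectory shorter than one fit window")
  cand <- find_peak_candidates(x, y, min_separation)
  peaks <- numeric(0)
  wins <- NULL
  n_rej <- 0L
  for (i in cand) {
    lo <- x[i] - window / 2; hi <- x[i] + window / 2
    sel <- x >= lo & x <= hi
    if (sum(sel) < 3) { n_rej <- n_rej + 1L; next }
    xc <- x[sel] - x[i]
    cf <- stats::lm.fit(cbind(1, xc, xc^2), y[sel])$coefficients
    if (is.na(cf[3]) || cf[3] >= 0) {
      warning("peak near t = ", signif(x[i], 4),
              " h rejected: window not concave")
      n_rej <- n_rej + 1L
      next
    }
    vertex <- unname(x[i] - cf[2] / (2 * cf[3]))
    if (vertex < lo || vertex > hi) {
      warning("peak near t = ", signif(x[i], 4),
              " h rejected: vertex outside window")
      n_rej <- n_rej + 1L
      next
    }
    peaks <- c(peaks, vertex)
    wins <- rbind(wins, c(lo, hi))
  }
  ord <- order(peaks)
  structure(list(peak_times = peaks[ord],
                 period_estimate = if (length(peaks) >= 2)
                   mean(diff(peaks[ord])) else NA_real_,
                 windows = if (is.null(wins)) wins else wins[ord, , drop = FALSE],
                 n_rejected = n_rej,
                 series_id = xy$id),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("<peak_estimate '%s': %d peaks, period %.3f h>\n",
              x$series_id, length(x$peak_times), x$period_estimate))
  invisible(x)
}

#' Reject poorly fitting series
#'
#' Removes fits whose squared error exceeds `threshold` (default 10 in
#' normalized signal units, matching the 0-13 rejected wells typically seen
#' on a 96-well plate).
#'
#' @param fits list of `sinusoid_fit` objects.
#' @param threshold positive squared-error cutoff.
#' @return the retained fits, with attribute `n_rejected`.
#' @export
reject_outlier_fits <- function(fits, threshold = 10) {
  if (threshold <= 0) fail("threshold must be positive")
  err <- vapply(fits, `[[`, numeric(1), "squared_error")
  keep <- err <= threshold
  if (!any(keep)) fail("all ", length(fits), " fits exceed the error threshold")
  if (any(!keep))
    message(sum(!keep), " of ", length(fits),
            " fits rejected (squared error > ", threshold, ")")
  structure(fits[keep], n_rejected = sum(!keep))
}
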