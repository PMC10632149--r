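#' Regularly sampled time series on the session clock
#'
#' The basic container for every continuous channel (EEG, LFP, ECG,
#' respiration piezo, laser-Doppler flow). Sample `i` (1-based) is at time
#' `t0 + (i - 1) / sample_rate`, all in seconds on a single session clock
#' whose origin is the start of the recording.
#'
#' @param values numeric vector of samples; must be finite unless `na_ok`.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds (session clock, >= 0).
#' @param label channel name, e.g. `"eeg"`, `"ecg"`, `"ldf"`.
#' @param na_ok allow NA samples (used for masked traces such as pupil area).
#' @return an object of class `time_series`.
#' @export
#' @examples
#' ts <- time_series(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), 500)
#' ts_duration(ts)
time_series <- function(values, sample_rate, t0 = 0, label = "", na_ok = FALSE) {
  if (!is_scalar_num(sample_rate) || sample_rate <= 0)
    stop_validation("sample_rate must be a positive number")
  if (!is_scalar_num(t0) || t0 < 0)
    stop_validation("t0 must be >= 0 on the session clock")
  values <- as.numeric(values)
  if (!na_ok && anyNA(values))
    stop_validation("values contain NA; use na_ok = TRUE for masked traces")
  if (any(!is.finite(values) & !is.na(values)))
    stop_validation("values must be finite (or NA when masked)")
  structure(
    list(values = values, sample_rate = sample_rate, t0 = t0,
         label = as.character(label)),
    class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series '%s': %d samples @ %g Hz, t0 = %g s, %.1f s>\n",
              x$label, length(x$values), x$sample_rate, x$t0, ts_duration(x)))
  invisible(x)
}

#' Sample times of a time series
#' @param x a `time_series`.
#' @return numeric vector of times in seconds.
#' @export
ts_times <- function(x) x$t0 + (seq_along(x$values) - 1) / x$sample_rate

#' Duration of a time series in seconds
#' @param x a `time_series`.
#' @export
ts_duration <- function(x) length(x$values) / x$sample_rate

#' Extract the samples of a time series falling in a time window
#'
#' Half-open window `[start, end)` on the session clock.
#'
#' @param x a `time_series`.
#' @param start,end window bounds in seconds.
#' @return a `time_series` covering the window (t0 = time of first kept sample).
#' @export
ts_window <- function(x, start, end) {
  tt <- ts_times(x)
  keep <- tt >= start - 1e-9 & tt < end - 1e-9
  if (!any(keep)) stop_validation("window [", start, ", ", end, ") is empty")
  i <- range(which(keep))
  time_series(x$values[i[1]:i[2]], x$sample_rate, t0 = tt[i[1]],
              label = x$label, na_ok = TRUE)
}

#' Cut event-aligned segments out of a continuous trace
#'
#' For every event onset, extracts `round((pre + post) * sample_rate)` samples
#' covering `[onset - pre, onset + post)`, with the returned time axis
#' relative to the onset (`t0 = -pre`). Events whose window sticks out of the
#' recorded extent are dropped with a warning.
#'
#' @param series a `time_series`.
#' @param events a `data.frame` with an `onset` column (e.g. a laser event
#'   table) or a numeric vector of onset times in seconds.
#' @param pre,post seconds before/after each onset (both >= 0).
#' @return a list of `time_series` segments, one per retained event, each
#'   carrying the originating onset as attribute `"onset"`.
#' @export
cut_windows <- function(series, events, pre, post) {
  stopifnot(inherits(series, "time_series"))
  if (pre < 0 || post < 0) stop_validation("pre and post must be >= 0")
  onsets <- if (is.data.frame(events)) events$onset else as.numeric(events)
  if (length(onsets) == 0L) return(list())
  n <- round((pre + post) * series$sample_rate)
  out <- list()
  dropped <- 0L
  for (on in onsets) {
    i0 <- round((on - pre - series$t0) * series$sample_rate) + 1
    i1 <- i0 + n - 1
    if (i0 < 1 || i1 > length(series$values)) {
      dropped <- dropped + 1L
      next
    }
    seg <- time_series(series$values[i0:i1], series$sample_rate, t0 = 0,
                       label = series$label, na_ok = TRUE)
    seg$t0 <- -pre  # relative time axis; constructor enforces t0 >= 0
    attr(seg, "onset") <- on
    out[[length(out) + 1L]] <- seg
  }
  if (dropped > 0L)
    warning(dropped, " event(s) too close to the series edge were dropped")
  out
}
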