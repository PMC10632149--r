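# Cardiovascular and cerebral-blood-flow signal metrics: ECG -> heart rate,
# respiration rate, stated quantification windows, shifted-subtraction
# adaptation isolation, and the six laser-Doppler flowmetry metrics.

# Local-maximum peak detection with a minimum height and refractory distance.
find_peaks <- function(x, min_height, min_dist_samples) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  taken <- integer(0)
  for (i in cand) {
    if (!length(taken) || all(abs(taken - i) >= min_dist_samples))
      taken <- c(taken, i)
  }
  sort(taken)
}

#' Heart rate from ECG R peaks
#'
#' The ECG is band-passed 10-50 Hz (zero phase) to aid peak detection;
#' positive R peaks are found with an adaptive height threshold (4 x the
#' median absolute deviation of the filtered trace) and a refractory minimum
#' R-R interval. Instantaneous rate 60/RR is interpolated to the sample grid
#' and smoothed with a 1-s sliding window.
#'
#' @param ecg a [time_series] (sample rate >= 200 Hz).
#' @param band bandpass edges in Hz.
#' @param smooth_window smoothing window in seconds (1).
#' @param min_rr refractory minimum R-R interval in seconds (0.04; a mouse at
#'   600 bpm has RR = 0.1 s).
#' @param mad_mult height threshold in MADs of the filtered trace.
#' @return object of class `rate_trace`: list with `bpm` (a smoothed
#'   [time_series]), `peak_times` (s).
#' @export
heart_rate <- function(ecg, band = c(10, 50), smooth_window = 1,
                       min_rr = 0.04, mad_mult = 4) {
  stopifnot(inherits(ecg, "time_series"))
  fs <- ecg$sample_rate
  if (fs < 200) stop_validation("ECG sample rate must be >= 200 Hz")
  bt <- signal::butter(3, band / (fs / 2), type = "pass")
  f <- as.numeric(signal::filtfilt(bt, ecg$values))
  thr <- mad_mult * stats::mad(f)
  pk <- find_peaks(f, thr, round(min_rr * fs))
  if (length(pk) < 3L) stop("too few R peaks detected to form a rate trace")
  pt <- ts_times(ecg)[pk]
  rr <- diff(pt)
  inst <- 60 / rr
  tt <- ts_times(ecg)
  bpm <- stats::approx(pt[-1], inst, xout = tt, rule = 2)$y
  bpm <- moving_mean(bpm, smooth_window * fs)
  structure(
    list(bpm = time_series(bpm, fs, t0 = ecg$t0, label = "bpm"),
         peak_times = pt),
    class = "rate_trace")
}

#' Respiration rate from the piezo transducer
#'
#' Breath events are detected after 1-10 Hz band-limiting, converted to
#' breaths/min, interpolated and smoothed exactly as the heart rate.
#'
#' @param piezo a [time_series].
#' @param band breathing band in Hz.
#' @param smooth_window smoothing window in seconds.
#' @param min_interval refractory minimum breath interval in seconds.
#' @return a `rate_trace` (`bpm` in breaths/min), or rate `NA` everywhere if
#'   no breaths are detected (reported missing, not an error).
#' @export
respiration_rate <- function(piezo, band = c(1, 10), smooth_window = 1,
                             min_interval = 0.1) {
  stopifnot(inherits(piezo, "time_series"))
  fs <- piezo$sample_rate
  tt <- ts_times(piezo)
  no_breaths <- function() structure(
    list(bpm = time_series(rep(NA_real_, length(tt)), fs, t0 = piezo$t0,
                           label = "rr", na_ok = TRUE),
         peak_times = numeric(0)),
    class = "rate_trace")
  if (stats::sd(piezo$values) < 1e-12) return(no_breaths())
  bt <- signal::butter(3, pmin(band / (fs / 2), 0.99), type = "pass")
  f <- as.numeric(signal::filtfilt(bt, piezo$values))
  # a sinusoidal breath peaks at ~0.95 x its scaled MAD (1.4826 factor), so
  # the threshold must sit below that
  thr <- 0.7 * stats::mad(f)
  pk <- find_peaks(f, thr, round(min_interval * fs))
  if (length(pk) < 3L) return(no_breaths())
  pt <- tt[pk]
  inst <- 60 / diff(pt)
  bpm <- stats::approx(pt[-1], inst, xout = tt, rule = 2)$y
  bpm <- moving_mean(bpm, smooth_window * fs)
  structure(
    list(bpm = time_series(bpm, fs, t0 = piezo$t0, label = "rr"),
         peak_times = pt),
    class = "rate_trace")
}

#' Normalize a rate trace to its pre-laser baseline, per stimulation
#'
#' Each stimulation window is normalized by the mean rate over the
#' `baseline` seconds preceding its onset, so the baseline average is 1.
#'
#' @param trace a `rate_trace` (from [heart_rate()] or [respiration_rate()]).
#' @param lasers laser event table (or onset vector).
#' @param baseline baseline length in seconds before onset (30; the paper's
#'   range is 30 s to 1 min).
#' @param post seconds after laser end to keep in each segment (60).
#' @return list of normalized [time_series] segments (time axis relative to
#'   onset), one per laser; errors if a baseline contains no rate samples.
#' @export
normalize_rate_trace <- function(trace, lasers, baseline = 30, post = 60) {
  stopifnot(inherits(trace, "rate_trace"))
  onsets <- if (is.data.frame(lasers)) lasers$onset else as.numeric(lasers)
  durs <- if (is.data.frame(lasers)) lasers$duration else rep(30, length(onsets))
  bpm <- trace$bpm
  tt <- ts_times(bpm)
  out <- list()
  for (i in seq_along(onsets)) {
    on <- onsets[i]
    bl <- tt >= on - baseline & tt < on
    base <- mean(bpm$values[bl], na.rm = TRUE)
    if (!any(bl) || !is.finite(base) || base <= 0)
      stop("no usable rate samples in the 30-s baseline before laser at ",
           on, " s")
    sel <- tt >= on - baseline & tt < on + durs[i] + post
    seg <- time_series(bpm$values[sel] / base, bpm$sample_rate, t0 = 0,
                       label = bpm$label, na_ok = TRUE)
    seg$t0 <- tt[which(sel)[1]] - on
    attr(seg, "onset") <- on
    out[[i]] <- seg
  }
  out
}

#' Mean rate change in the stated stimulation and post-stimulation windows
#'
#' Heart rate uses a 6-24 s window in the centre of the stimulation period
#' and a 30-60 s post window (relative to laser onset); respiration uses
#' 6-15 s and 36-45 s.
#'
#' @param segment a normalized segment from [normalize_rate_trace()] (time
#'   axis relative to laser onset).
#' @param kind `"hr"` or `"rr"` (selects the stated windows), or supply
#'   `stim_window` / `post_window` directly.
#' @param stim_window,post_window windows in seconds relative to onset.
#' @return list with `stim` and `post` mean normalized rates (`post` is NA
#'   when the segment ends before the post window).
#' @export
stim_window_stats <- function(segment, kind = c("hr", "rr"),
                              stim_window = NULL, post_window = NULL) {
  kind <- match.arg(kind)
  if (is.null(stim_window))
    stim_window <- if (kind == "hr") c(6, 24) else c(6, 15)
  if (is.null(post_window))
    post_window <- if (kind == "hr") c(30, 60) else c(36, 45)
  tt <- ts_times(segment)
  win_mean <- function(w) {
    sel <- tt >= w[1] & tt < w[2]
    if (!any(sel)) return(NA_real_)
    mean(segment$values[sel], na.rm = TRUE)
  }
  list(stim = win_mean(stim_window), post = win_mean(post_window))
}

#' Shifted self-subtraction to isolate drug effects during adaptation trains
#'
#' `output(t) = trace(t) - trace(t - shift)`, defined for `t >= shift`: any
#' component periodic at the stimulation period (the shift) cancels, leaving
#' the drug transient. Shifts of 10 s (PBG) and 40 s (PE) match the
#' stimulation schedules used with those agents.
#'
#' @param trace a [time_series].
#' @param shift shift in seconds (> 0 and shorter than the trace).
#' @return a [time_series] starting at `t0 + shift`.
#' @export
adaptation_subtract <- function(trace, shift) {
  stopifnot(inherits(trace, "time_series"))
  if (shift <= 0) stop_validation("shift must be > 0")
  s <- round(shift * trace$sample_rate)
  n <- length(trace$values)
  if (s >= n) stop_validation("shift of ", shift, " s exceeds the trace duration")
  time_series(trace$values[(s + 1):n] - trace$values[1:(n - s)],
              trace$sample_rate, t0 = trace$t0 + s / trace$sample_rate,
              label = trace$label, na_ok = TRUE)
}

#' The six laser-Doppler flowmetry metrics of a stimulation trial
#'
#' The raw LDF trace is normalized to the mean of the 30 s before laser
#' onset and median-filtered over 500 ms; the metrics are then, relative to
#' laser onset: (1) `latency_50`, time to fall below 50% of baseline;
#' (2) `min_during_stim`, the minimum over the stimulation window;
#' (3) `fwhm_transit`, the time spent below the half-minimum level
#' `(1 + min)/2`; (4) `late_mean`, the mean over the 100 s before trial end;
#' (5) `recovery_duration`, time after stimulus end to first return to
#' baseline (>= 1); (6) `rate_coefficient`, the ratio of the ascent slope to
#' the magnitude of the descent slope within the stimulation window
#' (least-squares fits over the limbs flanking the minimum).
#'
#' @param ldf a [time_series] covering baseline, a 30-s stimulation, and a
#'   tail of at least 100 s.
#' @param laser_onset laser onset in seconds.
#' @param stim_duration stimulation length in seconds (30).
#' @param baseline baseline length in seconds (30).
#' @param median_window median filter window in seconds (0.5).
#' @return object of class `ldf_metrics`: the six metrics plus `t_min`
#'   (time of the flow minimum, relative to onset) and the normalized trace.
#'   `latency_50` and `recovery_duration` are NA when never crossed.
#' @export
ldf_metrics <- function(ldf, laser_onset, stim_duration = 30, baseline = 30,
                        median_window = 0.5) {
  stopifnot(inherits(ldf, "time_series"))
  fs <- ldf$sample_rate
  tt <- ts_times(ldf)
  bl <- tt >= laser_onset - baseline & tt < laser_onset
  if (!any(bl)) stop_validation("no baseline samples before laser onset")
  v <- ldf$values / mean(ldf$values[bl])
  k <- round(median_window * fs)
  if (k %% 2 == 0) k <- k + 1
  if (k >= 3 && length(v) > k) v <- stats::runmed(v, k, endrule = "median")
  rel <- tt - laser_onset
  stim <- rel >= 0 & rel < stim_duration
  post <- rel >= stim_duration

  below50 <- which(stim & v < 0.5)
  latency_50 <- if (length(below50)) rel[below50[1]] else NA_real_
  i_min <- which(stim)[which.min(v[stim])]
  min_stim <- v[i_min]
  t_min <- rel[i_min]
  half_level <- (1 + min_stim) / 2
  below_half <- which(v < half_level & rel >= 0)
  fwhm <- if (length(below_half)) length(below_half) / fs else 0
  late_sel <- tt >= max(tt) - 100
  late_mean <- mean(v[late_sel])
  rec <- which(post & v >= 1)
  recovery <- if (length(rec)) rel[rec[1]] - stim_duration else NA_real_

  # limb delimitation: from last at-baseline sample before the minimum to the
  # minimum (descent), and from the minimum to the first return to baseline
  # inside the stimulation window (ascent)
  pre_min <- which(stim & rel <= t_min & v >= 1 - 1e-9)
  d_start <- if (length(pre_min)) max(pre_min) else which(stim)[1]
  post_min <- which(stim & rel >= t_min & v >= 1 - 1e-9)
  a_end <- if (length(post_min)) min(post_min) else max(which(stim))
  fit_slope <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(v[idx] ~ rel[idx]))[2])
  }
  slope_down <- fit_slope(d_start:i_min)
  slope_up <- fit_slope(i_min:a_end)
  rate_coefficient <- if (is.na(slope_down) || is.na(slope_up) ||
                          slope_down >= 0) NA_real_ else
    abs(slope_up) / abs(slope_down)

  structure(
    list(latency_50 = latency_50, min_during_stim = min_stim,
         fwhm_transit = fwhm, late_mean = late_mean,
         recovery_duration = recovery, rate_coefficient = rate_coefficient,
         t_min = t_min,
         normalized = time_series(v, fs, t0 = ldf$t0, label = "ldf_norm")),
    class = "ldf_metrics")
}

#' @export
print.ldf_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<ldf_metrics: latency50 %.3g s, min %.3g, fwhm %.3g s, late %.3g, ",
    "recovery %.3g s, rate coeff %.3g>\n"),
    x$latency_50, x$min_during_stim, x$fwhm_transit, x$late_mean,
    x$recovery_duration, x$rate_coefficient))
  invisible(x)
}

#' Align trial traces to syncope onset and average
#'
#' @param traces list of [time_series], one per trial (on the session clock).
#' @param onsets syncope onset per trial (seconds).
#' @param pre,post seconds kept around each onset.
#' @return list with `mean` (a [time_series] on the relative axis),
#'   `segments` (list of aligned trials); NULL with a message when `onsets`
#'   is empty.
#' @export
align_to_syncope <- function(traces, onsets, pre = 30, post = 60) {
  if (!length(onsets)) {
    message("no syncope events; nothing to align")
    return(NULL)
  }
  stopifnot(length(traces) == length(onsets))
  segs <- list()
  for (i in seq_along(traces)) {
    s <- cut_windows(traces[[i]], onsets[i], pre, post)
    if (length(s)) segs[[length(segs) + 1L]] <- s[[1]]
  }
  if (!length(segs)) return(NULL)
  M <- do.call(rbind, lapply(segs, `[[`, "values"))
  avg <- time_series(colMeans(M), segs[[1]]$sample_rate, t0 = 0,
                     label = traces[[1]]$label, na_ok = TRUE)
  avg$t0 <- -pre
  list(mean = avg, segments = segs)
}

#' Per-trial event sequence around syncope induction
#'
#' Orders the characteristic events of each 20-Hz trial: heart-rate minimum,
#' flow (LDF) minimum, the 50% power drop (= syncope onset), and the
#' eye-roll annotation when provided.
#'
#' @param hr a `rate_trace` (smoothed bpm) or NULL.
#' @param ldf an LDF [time_series] or NULL.
#' @param syncope syncope event table (`laser_onset`, `onset`).
#' @param lasers laser event table.
#' @param eyeroll optional data.frame (`laser_onset`, `time`) of manual
#'   eye-roll annotations.
#' @return `data.frame` per trial: times (s, relative to laser onset) of
#'   `hr_min`, `ldf_min`, `power_drop`, `eyeroll`.
#' @export
syncope_event_sequence <- function(hr = NULL, ldf = NULL, syncope, lasers,
                                   eyeroll = NULL) {
  stopifnot(nrow(syncope) >= 1L)
  rows <- lapply(seq_len(nrow(syncope)), function(i) {
    on <- syncope$laser_onset[i]
    li <- which.min(abs(lasers$onset - on))
    dur <- lasers$duration[li]
    win_min <- function(ts_obj) {
      if (is.null(ts_obj)) return(NA_real_)
      tt <- ts_times(ts_obj)
      sel <- tt >= on & tt < on + dur
      if (!any(sel)) return(NA_real_)
      tt[sel][which.min(ts_obj$values[sel])] - on
    }
    hr_min <- if (!is.null(hr)) win_min(hr$bpm) else NA_real_
    ldf_min <- win_min(ldf)
    er <- NA_real_
    if (!is.null(eyeroll)) {
      m <- eyeroll[abs(eyeroll$laser_onset - on) < 1e-6, ]
      if (nrow(m)) er <- m$time[1] - on
    }
    data.frame(laser_onset = on, hr_min = hr_min, ldf_min = ldf_min,
               power_drop = syncope$onset[i] - on, eyeroll = er)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
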