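# Behaviour feature extraction: motion-energy SVD of face movies, whisking
# norm, pupil ellipse area with blink masking, and baseline normalization.

#' Segmented SVD of a face movie and its motion energy
#'
#' The absolute motion energy at each frame is `|frame_t - frame_{t-1}|`
#' (first frame set to 0 by convention). Movies are too large for one SVD, so
#' spatial bases are computed per time segment and merged with a second SVD
#' over the concatenated segment bases; the movie (and motion energy) are then
#' projected onto the top `n_components` merged components.
#'
#' @param movie numeric matrix `pixels x T` on a fixed pixel grid.
#' @param n_components components to keep (250 for real sessions; clipped
#'   with a warning if it exceeds `min(pixels, segment frames)`).
#' @param segment_length frames per SVD segment (default 1000).
#' @return list with `x_movie`, `x_motion` (each `n_components x T`),
#'   `basis_movie`, `basis_motion` (`pixels x n_components`).
#' @export
motion_energy_svd <- function(movie, n_components = 250,
                              segment_length = 1000) {
  stopifnot(is.matrix(movie), ncol(movie) >= 2L)
  motion <- cbind(0, abs(movie[, -1, drop = FALSE] -
                           movie[, -ncol(movie), drop = FALSE]))
  seg_basis <- function(M) {
    Tt <- ncol(M)
    starts <- seq(1L, Tt, by = segment_length)
    nc_seg <- min(n_components, nrow(M), segment_length)
    bases <- lapply(starts, function(s) {
      seg <- M[, s:min(s + segment_length - 1L, Tt), drop = FALSE]
      k <- min(nc_seg, ncol(seg))
      svd(seg, nu = k, nv = 0)$u
    })
    U <- do.call(cbind, bases)
    k <- min(n_components, nrow(M), ncol(U))
    svd(U, nu = k, nv = 0)$u
  }
  nc_eff <- min(n_components, nrow(movie), ncol(movie))
  if (nc_eff < n_components)
    warning("n_components clipped to ", nc_eff)
  Um <- seg_basis(movie)
  Ue <- seg_basis(motion)
  list(x_movie = crossprod(Um, movie),
       x_motion = crossprod(Ue, motion),
       basis_movie = Um, basis_motion = Ue)
}

#' Whisking trace: L2 norm of the top-10 whisker motion components
#'
#' @param whisker_motion_svd matrix `>= 10 x T`; with fewer than 10 components
#'   all available ones are used, with a warning.
#' @return numeric vector of length `T`.
#' @export
whisking_trace <- function(whisker_motion_svd) {
  stopifnot(is.matrix(whisker_motion_svd))
  k <- min(10L, nrow(whisker_motion_svd))
  if (k < 10L) warning("fewer than 10 whisker components; using all ", k)
  sqrt(colSums(whisker_motion_svd[seq_len(k), , drop = FALSE]^2))
}

#' Blink detection from the eye dark-pixel count
#'
#' A frame is a blink when the count of eye-ROI pixels darker than the
#' saturation threshold falls strictly below `area_threshold` (the threshold
#' is kept identical across animals).
#'
#' @param eye_dark_pixel_count per-frame pixel counts.
#' @param area_threshold pixel-count threshold.
#' @return logical blink flags per frame.
#' @export
blink_detect <- function(eye_dark_pixel_count, area_threshold) {
  as.numeric(eye_dark_pixel_count) < area_threshold
}

#' Pupil area from four keypoints, with confidence and blink masking
#'
#' Keypoint coordinates are median filtered (window of 5 frames, about
#' 160 ms at 30 Hz); the vertical axis is `|top - bottom|`, the horizontal
#' `|left - right|`, and the area is that of the ellipse with those axes,
#' `pi * a/2 * b/2`. Frames with any keypoint confidence below
#' `conf_threshold`, a blink, or a degenerate (zero-length) axis are set
#' undefined (`NA`) and are never interpolated.
#'
#' @param keypoints array `4 x 2 x T` (rows top, bottom, left, right;
#'   columns x, y).
#' @param confidences matrix `4 x T` of tracking likelihoods (or NULL to skip
#'   confidence masking).
#' @param blink_mask logical vector of blink frames (or NULL).
#' @param median_window median filter window in frames (odd, default 5).
#' @param conf_threshold likelihood threshold (0.75).
#' @return object of class `pupil_trace`: list with `area` (pixel^2, NA where
#'   undefined), `mask` (TRUE = undefined), `axes` (2 x T).
#' @export
pupil_area <- function(keypoints, confidences = NULL, blink_mask = NULL,
                       median_window = 5, conf_threshold = 0.75) {
  stopifnot(length(dim(keypoints)) == 3L, dim(keypoints)[1] == 4L,
            dim(keypoints)[2] == 2L)
  Tt <- dim(keypoints)[3]
  medf <- function(v) {
    if (Tt < median_window) return(v)
    stats::runmed(v, median_window, endrule = "median")
  }
  kp <- keypoints
  for (i in 1:4) for (j in 1:2) kp[i, j, ] <- medf(keypoints[i, j, ])
  vert <- sqrt(colSums((kp[1, , ] - kp[2, , ])^2))
  horiz <- sqrt(colSums((kp[3, , ] - kp[4, , ])^2))
  area <- pi * (vert / 2) * (horiz / 2)
  mask <- rep(FALSE, Tt)
  if (!is.null(confidences))
    mask <- mask | apply(confidences < conf_threshold, 2, any)
  if (!is.null(blink_mask)) mask <- mask | as.logical(blink_mask)
  degen <- vert <= 0 | horiz <= 0
  if (any(degen & !mask))
    message(sum(degen & !mask), " frame(s) with a degenerate pupil axis set undefined")
  mask <- mask | degen
  area[mask] <- NA_real_
  structure(list(area = area, mask = mask, axes = rbind(vert, horiz)),
            class = "pupil_trace")
}

#' Event-aligned baseline normalization of a behaviour trace
#'
#' For each event onset the trace is divided by its mean over the
#' event-specific baseline window (e.g. the 30 s before laser onset, or
#' -6 to -4 s before syncope onset), and a summary mean over the stated
#' post-event window is returned alongside. Undefined samples (NA) are
#' ignored in the means; events with an empty, undefined or zero baseline are
#' skipped with a warning.
#'
#' @param trace a [time_series] (NA allowed) or numeric vector.
#' @param onsets event onset times in seconds.
#' @param sample_rate required if `trace` is a plain vector.
#' @param baseline_window `c(lo, hi)` in seconds relative to onset
#'   (default `c(-30, 0)`).
#' @param summary_window `c(lo, hi)` relative to onset for the summary mean
#'   (default `c(0, 5)`).
#' @return list with `segments` (normalized [time_series], one per retained
#'   event, relative time axis) and `summaries` (named numeric vector of
#'   post-event means, NA for skipped events).
#' @export
normalize_to_baseline <- function(trace, onsets, sample_rate = NULL,
                                  baseline_window = c(-30, 0),
                                  summary_window = c(0, 5)) {
  if (!inherits(trace, "time_series"))
    trace <- time_series(trace, sample_rate, na_ok = TRUE)
  tt <- ts_times(trace)
  segments <- list()
  summaries <- rep(NA_real_, length(onsets))
  for (i in seq_along(onsets)) {
    on <- onsets[i]
    bl <- tt >= on + baseline_window[1] & tt < on + baseline_window[2]
    base <- mean(trace$values[bl], na.rm = TRUE)
    if (!any(bl) || !is.finite(base) || base == 0) {
      warning("event at ", on, " s skipped: empty or zero baseline")
      next
    }
    lo <- on + baseline_window[1]
    hi <- max(on + summary_window[2], on + baseline_window[2])
    sel <- tt >= lo & tt < hi
    seg <- time_series(trace$values[sel] / base, trace$sample_rate,
                       t0 = 0, label = trace$label, na_ok = TRUE)
    seg$t0 <- tt[which(sel)[1]] - on
    attr(seg, "onset") <- on
    segments[[length(segments) + 1L]] <- seg
    sw <- tt >= on + summary_window[1] & tt < on + summary_window[2]
    summaries[i] <- mean(trace$values[sw], na.rm = TRUE) / base
  }
  names(summaries) <- paste0("event_", seq_along(onsets))
  list(segments = segments, summaries = summaries)
}
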