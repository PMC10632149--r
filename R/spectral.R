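# Wavelet / FFT power analysis of EEG and LFP, syncope detection, and the
# Monte Carlo cluster permutation test in the time x frequency plane.

#' Default 80 log-spaced wavelet centre frequencies (0.5 to 120 Hz)
#' @export
wavelet_freqs <- function(n = 80, fmin = 0.5, fmax = 120)
  exp(seq(log(fmin), log(fmax), length.out = n))

#' Remove 60-Hz line noise with a 59-61 Hz band-stop filter
#'
#' Zero-phase Butterworth band-stop (applied forward and backward), attenuating
#' the 60-Hz component by well over 20 dB while leaving the passband
#' (< 55 Hz, > 65 Hz) essentially untouched.
#'
#' @param series a [time_series]; `sample_rate` must exceed `2 * band[2]`.
#' @param band stop band in Hz, default `c(59, 61)`.
#' @param order Butterworth order (per side), default 2.
#' @return filtered [time_series].
#' @export
notch_filter <- function(series, band = c(59, 61), order = 2) {
  stopifnot(inherits(series, "time_series"))
  fs <- series$sample_rate
  if (fs <= 2 * band[2])
    stop_validation("sample_rate ", fs, " Hz too low for a ", band[1], "-",
                    band[2], " Hz notch")
  bt <- signal::butter(order, band / (fs / 2), type = "stop")
  out <- series
  out$values <- as.numeric(signal::filtfilt(bt, series$values))
  out
}

# Analytic generalized Morse wavelet, frequency domain, amplitude-normalized so
# the peak response is identical across centre frequencies (which makes a pure
# sinusoid localize at the nearest centre-frequency bin).
# gamma = 3 (symmetric, "airy" family), beta = 27 => sqrt(beta*gamma) = 9,
# about six oscillations under the envelope.
morse_filter <- function(n, fs, fc, gamma = 3, beta = 27) {
  w <- 2 * pi * (0:(n - 1)) / n          # digital radian frequency
  w[w > pi] <- w[w > pi] - 2 * pi        # negative frequencies
  wp <- (beta / gamma)^(1 / gamma)       # peak of omega^beta exp(-omega^gamma)
  s <- wp / (2 * pi * fc / fs)           # scale mapping peak to fc
  H <- numeric(n)
  pos <- w > 0
  x <- s * w[pos]
  H[pos] <- 2 * exp(beta * (log(x) - log(wp)) - (x^gamma - wp^gamma))
  H
}

#' Morse-wavelet power spectrogram with per-frequency baseline normalization
#'
#' Computes power with 80 logarithmically spaced analytic Morse wavelets
#' (0.5-120 Hz by default) and, if a baseline window is given (or by default
#' the whole trace), divides each frequency row by its mean power during the
#' baseline so the baseline mean is exactly 1 per frequency.
#'
#' @param series a [time_series] (notch-filter first for mains-contaminated
#'   recordings).
#' @param baseline an [analysis_window] on the session clock, or `NULL` to use
#'   the whole trace as its own baseline.
#' @param freqs wavelet centre frequencies in Hz (strictly increasing).
#' @param gamma,beta Morse family parameters.
#' @param time_decimate keep every `time_decimate`-th power sample (the wavelet
#'   envelope is much slower than the raw sampling, so decimation loses
#'   nothing for band-power work while bounding memory).
#' @param normalize divide by baseline power per frequency (default TRUE).
#' @return object of class `wavelet_spectrogram`: list with `freqs`, `times`,
#'   `power` (`length(freqs) x length(times)`), `baseline_window`,
#'   `normalized`, `source`.
#' @export
wavelet_power <- function(series, baseline = NULL, freqs = wavelet_freqs(),
                          gamma = 3, beta = 27, time_decimate = 1L,
                          normalize = TRUE) {
  stopifnot(inherits(series, "time_series"))
  if (is.unsorted(freqs, strictly = TRUE))
    stop_validation("freqs must be strictly increasing")
  n <- length(series$values)
  fs <- series$sample_rate
  if (n / fs < 3 / freqs[1])
    warning("trace shorter than a few cycles of the lowest frequency; ",
            "low-frequency rows will be unreliable")
  tt <- ts_times(series)
  keep <- seq(1L, n, by = as.integer(time_decimate))
  times <- tt[keep]
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "analysis_window"))
    bl_idx <- which(times >= baseline$start & times < baseline$end)
    if (!length(bl_idx))
      stop_validation("baseline window contains no spectrogram samples")
  } else {
    bl_idx <- seq_along(times)
  }
  fx <- stats::fft(series$values)
  power <- matrix(0, nrow = length(freqs), ncol = length(keep))
  for (k in seq_along(freqs)) {
    H <- morse_filter(n, fs, freqs[k], gamma, beta)
    wk <- stats::fft(fx * H, inverse = TRUE) / n
    p <- (Mod(wk)^2)[keep]
    if (normalize) {
      mu <- mean(p[bl_idx])
      if (!is.finite(mu) || mu <= 0)
        stop("zero baseline power at frequency ", signif(freqs[k], 4), " Hz")
      p <- p / mu
    }
    power[k, ] <- p
  }
  structure(
    list(freqs = freqs, times = times, power = power,
         baseline_window = baseline, normalized = normalize,
         source = series$label),
    class = "wavelet_spectrogram")
}

#' @export
print.wavelet_spectrogram <- function(x, ...) {
  cat(sprintf("<wavelet_spectrogram '%s': %d freqs %.2g-%.4g Hz x %d times%s>\n",
              x$source, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), if (x$normalized) ", baseline-normalized" else ""))
  invisible(x)
}

#' Normalize a spectrogram to its baseline, per frequency row
#'
#' Divides each frequency row by its mean over the baseline columns so the
#' baseline mean is exactly 1 per row. Idempotent: renormalizing with the
#' same baseline is a no-op.
#'
#' @param spec a `wavelet_spectrogram`.
#' @param baseline an [analysis_window], or NULL to reuse the spectrogram's
#'   stored baseline (whole extent if none).
#' @return the normalized `wavelet_spectrogram`.
#' @export
normalize_spectrogram <- function(spec, baseline = NULL) {
  stopifnot(inherits(spec, "wavelet_spectrogram"))
  baseline <- baseline %||% spec$baseline_window
  cols <- if (is.null(baseline)) seq_along(spec$times) else
    which(spec$times >= baseline$start & spec$times < baseline$end)
  if (!length(cols)) stop_validation("baseline window contains no samples")
  mu <- rowMeans(spec$power[, cols, drop = FALSE])
  bad <- which(!is.finite(mu) | mu <= 0)
  if (length(bad))
    stop("zero baseline power at frequency ", signif(spec$freqs[bad[1]], 4),
         " Hz")
  spec$power <- spec$power / mu
  spec$baseline_window <- baseline
  spec$normalized <- TRUE
  spec
}

# Band-average normalized power trace of a spectrogram.
band_mean_power <- function(spec, band) {
  rows <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(rows)) stop_validation("band outside spectrogram frequencies")
  colMeans(spec$power[rows, , drop = FALSE])
}

#' Detect a syncope bout from broadband power loss
#'
#' The 8-100 Hz band-average of a baseline-normalized spectrogram is smoothed
#' with a centred moving mean; syncope onset is the first time after the laser
#' onset at which smoothed power drops below `onset_frac` (50% of baseline),
#' and offset the first subsequent time it recovers above `offset_frac` (80%).
#'
#' @param spec a normalized `wavelet_spectrogram`.
#' @param laser_onset laser onset time in seconds (search starts here); use
#'   `-Inf` to search the whole spectrogram.
#' @param band frequency band in Hz, default `c(8, 100)`.
#' @param onset_frac,offset_frac crossing fractions (0.5 / 0.8).
#' @param smooth_window moving-mean window in seconds (default 1).
#' @return a one-row `data.frame` (`onset`, `offset`, `laser_onset`, `band_lo`,
#'   `band_hi`, `source`) or `NULL` when power never crosses `onset_frac`.
#'   `offset` is `NA` when power never recovers.
#' @export
detect_syncope <- function(spec, laser_onset = -Inf, band = c(8, 100),
                           onset_frac = 0.5, offset_frac = 0.8,
                           smooth_window = 1) {
  stopifnot(inherits(spec, "wavelet_spectrogram"))
  if (!spec$normalized) stop_validation("spectrogram must be baseline-normalized")
  p <- band_mean_power(spec, band)
  dt <- stats::median(diff(spec$times))
  sm <- moving_mean(p, smooth_window / dt)
  cand <- which(sm < onset_frac & spec$times >= laser_onset)
  if (!length(cand)) return(NULL)
  i_on <- cand[1]
  rec <- which(sm > offset_frac & seq_along(sm) > i_on)
  offset <- if (length(rec)) spec$times[rec[1]] else NA_real_
  data.frame(onset = spec$times[i_on], offset = offset,
             laser_onset = if (is.finite(laser_onset)) laser_onset else NA_real_,
             band_lo = band[1], band_hi = band[2],
             source = spec$source, stringsAsFactors = FALSE)
}

#' Light-on minus light-off mean power map
#'
#' @param on_trials,off_trials lists of `wavelet_spectrogram`s (or plain
#'   matrices) on identical frequency/time grids.
#' @return matrix `mean(on) - mean(off)`, elementwise.
#' @export
light_contrast_map <- function(on_trials, off_trials) {
  as_mat <- function(x) if (inherits(x, "wavelet_spectrogram")) x$power else x
  on <- lapply(on_trials, as_mat)
  off <- lapply(off_trials, as_mat)
  if (!length(on) || !length(off))
    stop_validation("need at least one trial per condition")
  d <- dim(on[[1]])
  for (m in c(on, off))
    if (!identical(dim(m), d)) stop_validation("trial grids do not match")
  Reduce(`+`, on) / length(on) - Reduce(`+`, off) / length(off)
}

# Union-find connected components, 4-connectivity, on a logical matrix.
# Returns integer sizes of the components (possibly empty vector).
component_sizes <- function(mask) {
  idx <- which(mask)
  npix <- length(idx)
  if (npix == 0L) return(integer(0))
  nr <- nrow(mask)
  pos <- integer(length(mask))
  pos[idx] <- seq_len(npix)
  parent <- seq_len(npix)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (q in seq_len(npix)) {
    j <- idx[q]
    # right neighbour (j + nr), below neighbour (j + 1 unless bottom row)
    if (j + nr <= length(mask) && pos[j + nr] > 0L) {
      a <- find(q); b <- find(pos[j + nr])
      if (a != b) parent[a] <- b
    }
    if (j %% nr != 0L && pos[j + 1L] > 0L) {
      a <- find(q); b <- find(pos[j + 1L])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(npix), find, integer(1))
  as.integer(table(roots))
}

# Label map (same algorithm), for reporting cluster extents.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  npix <- length(idx)
  pos <- integer(length(mask))
  pos[idx] <- seq_len(npix)
  parent <- seq_len(npix)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (q in seq_len(npix)) {
    j <- idx[q]
    if (j + nr <= length(mask) && pos[j + nr] > 0L) {
      a <- find(q); b <- find(pos[j + nr])
      if (a != b) parent[a] <- b
    }
    if (j %% nr != 0L && pos[j + 1L] > 0L) {
      a <- find(q); b <- find(pos[j + 1L])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(npix), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Monte Carlo cluster permutation test for time x frequency power maps
#'
#' Shuffles trial labels between the light-on and light-off conditions to
#' build (a) a per-pixel permutation distribution of condition differences,
#' whose tails define the cluster-forming threshold, and (b) a null
#' distribution of the maximum area of 4-connected suprathreshold clusters.
#' Observed clusters whose area exceeds the `1 - alpha_per_tail` quantile of
#' the matching-tail null are significant; the direction of change is kept.
#'
#' @param on_trials,off_trials lists of matrices (or `wavelet_spectrogram`s)
#'   on identical grids; at least 3 per condition recommended.
#' @param n_perm number of label permutations (>= 100; default 1000).
#' @param alpha_per_tail significance level per tail (default 0.025).
#' @param cluster_forming_p two-sided pixelwise permutation p threshold that
#'   forms clusters (default 0.05).
#' @param seed RNG seed for the permutations.
#' @param freqs,times optional axes used to report cluster extents in physical
#'   units.
#' @return object of class `cluster_test`: list with `clusters` (data.frame:
#'   sign, area, p, significant, and index/unit ranges), `n_perm`,
#'   `alpha_per_tail`, `difference` (the observed mean difference map).
#' @export
cluster_permutation_test <- function(on_trials, off_trials, n_perm = 1000,
                                     alpha_per_tail = 0.025,
                                     cluster_forming_p = 0.05, seed = NULL,
                                     freqs = NULL, times = NULL) {
  as_mat <- function(x) if (inherits(x, "wavelet_spectrogram")) x$power else x
  on <- lapply(on_trials, as_mat)
  off <- lapply(off_trials, as_mat)
  n_on <- length(on); n_off <- length(off)
  if (n_on < 1L || n_off < 1L) stop_validation("need trials in both conditions")
  if (n_on < 3L || n_off < 3L)
    warning("fewer than 3 trials per condition; permutation null is coarse")
  if (n_perm < 100L) stop_validation("n_perm must be >= 100")
  d <- dim(on[[1]])
  X <- cbind(do.call(cbind, lapply(on, as.vector)),
             do.call(cbind, lapply(off, as.vector)))
  ntr <- n_on + n_off
  obs <- rowMeans(X[, seq_len(n_on), drop = FALSE]) -
    rowMeans(X[, n_on + seq_len(n_off), drop = FALSE])

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  W <- matrix(0, ntr, n_perm)
  for (p in seq_len(n_perm)) {
    pick <- sample.int(ntr, n_on)
    W[pick, p] <- 1 / n_on
    W[-pick, p] <- -1 / n_off
  }
  D <- X %*% W  # pixels x n_perm null difference maps

  qs <- c(cluster_forming_p / 2, 1 - cluster_forming_p / 2)
  lo <- hi <- numeric(nrow(D))
  for (i in seq_len(nrow(D))) {
    q <- stats::quantile(D[i, ], qs, names = FALSE, type = 7)
    lo[i] <- q[1]; hi[i] <- q[2]
  }

  max_area <- function(v, thr_hi, thr_lo) {
    c(pos = {
        m <- matrix(v > thr_hi, d[1], d[2])
        s <- component_sizes(m); if (length(s)) max(s) else 0L
      },
      neg = {
        m <- matrix(v < thr_lo, d[1], d[2])
        s <- component_sizes(m); if (length(s)) max(s) else 0L
      })
  }
  null_max <- matrix(0L, 2, n_perm)
  for (p in seq_len(n_perm)) null_max[, p] <- max_area(D[, p], hi, lo)

  degenerate <- all(abs(D) < 1e-12) && all(abs(obs) < 1e-12)
  if (degenerate) warning("all trials identical: degenerate null, no clusters")

  clusters <- list()
  for (sign in c(1, -1)) {
    mask <- if (sign > 0) matrix(obs > hi, d[1], d[2]) else
      matrix(obs < lo, d[1], d[2])
    lab <- label_components(mask)
    nc <- max(lab)
    if (nc == 0L) next
    null_tail <- null_max[if (sign > 0) 1 else 2, ]
    for (ci in seq_len(nc)) {
      px <- which(lab == ci, arr.ind = TRUE)
      area <- nrow(px)
      pval <- (1 + sum(null_tail >= area)) / (n_perm + 1)
      clusters[[length(clusters) + 1L]] <- data.frame(
        sign = sign, area = area, p = pval,
        significant = pval <= alpha_per_tail,
        freq_lo = if (!is.null(freqs)) freqs[min(px[, 1])] else min(px[, 1]),
        freq_hi = if (!is.null(freqs)) freqs[max(px[, 1])] else max(px[, 1]),
        time_lo = if (!is.null(times)) times[min(px[, 2])] else min(px[, 2]),
        time_hi = if (!is.null(times)) times[max(px[, 2])] else max(px[, 2]))
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(sign = numeric(), area = numeric(), p = numeric(),
               significant = logical(), freq_lo = numeric(),
               freq_hi = numeric(), time_lo = numeric(), time_hi = numeric())
  clusters <- clusters[order(clusters$p, -clusters$area), , drop = FALSE]
  rownames(clusters) <- NULL
  structure(
    list(clusters = clusters, n_perm = n_perm,
         alpha_per_tail = alpha_per_tail,
         difference = matrix(obs, d[1], d[2])),
    class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  nsig <- sum(x$clusters$significant)
  cat(sprintf("<cluster_test: %d cluster(s), %d significant at %.3f per tail, %d permutations>\n",
              nrow(x$clusters), nsig, x$alpha_per_tail, x$n_perm))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Standard EEG band definitions for FFT band power
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"),
    lo = c(1, 4, 8, 13, 30, 61),
    hi = c(4, 8, 13, 30, 59, 120))
}

#' FFT band power in 2-s segments
#'
#' Non-overlapping segments (trailing partial segment dropped); per-segment
#' periodogram power summed into the six standard bands: delta 1-4, theta
#' 4-8, alpha 8-13, beta 13-30, low gamma 30-59 and high gamma 61-120 Hz.
#' Band edges are half-open `[lo, hi)` so shared edges are not double-counted.
#' Apply [notch_filter()] first.
#'
#' @param series a [time_series] of duration >= `segment` seconds.
#' @param segment segment length in seconds (default 2).
#' @param taper `"none"` (default, plain FFT) or `"hann"`.
#' @return `data.frame` with `segment`, `t_start` and one power column per
#'   band; attribute `"bands"` holds the band table.
#' @export
band_power_fft <- function(series, segment = 2, taper = c("none", "hann")) {
  stopifnot(inherits(series, "time_series"))
  taper <- match.arg(taper)
  fs <- series$sample_rate
  nseg_len <- round(segment * fs)
  nseg <- floor(length(series$values) / nseg_len)
  if (nseg < 1L) stop_validation("series shorter than one ", segment, "-s segment")
  bands <- eeg_bands()
  win <- if (taper == "hann")
    0.5 * (1 - cos(2 * pi * seq_len(nseg_len) / (nseg_len + 1))) else
      rep(1, nseg_len)
  freqs <- (0:(nseg_len - 1)) * fs / nseg_len
  out <- matrix(0, nseg, nrow(bands))
  for (s in seq_len(nseg)) {
    x <- series$values[((s - 1) * nseg_len + 1):(s * nseg_len)] * win
    p <- Mod(stats::fft(x))^2 / nseg_len
    for (b in seq_len(nrow(bands))) {
      sel <- freqs >= bands$lo[b] & freqs < bands$hi[b]
      out[s, b] <- sum(p[sel])
    }
  }
  res <- data.frame(segment = seq_len(nseg),
                    t_start = series$t0 + (seq_len(nseg) - 1) * segment)
  res[bands$band] <- out
  attr(res, "bands") <- bands
  res
}
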