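# Synthetic-session generator. Every analysis stage is validated against
# sessions produced here, with programmed ground truth: behaviour-driven
# population spiking, pulse-locked laser responses with known latencies, a
# syncope state (broadband 8-100 Hz power loss plus spiking suppression),
# bradycardia/asystole in the ECG, a stimulus-locked cerebral-blood-flow dip,
# and pupil dilation with blink dropouts.

#' Configuration of the synthetic-session generator
#'
#' Defaults define the simulated study conditions: a 600-s head-fixed session
#' with four 30-s laser trains (5, 10 and 2 x 20 Hz), behaviour latents that
#' drive both the face-video SVD streams and unit firing, syncope 4-8 s after
#' each 20-Hz onset with an 80% broadband power drop and full spiking
#' suppression outside the periventricular zone, and the accompanying
#' cardiovascular profile.
#'
#' @param duration session length in seconds.
#' @param seed seed fixing all randomness end-to-end.
#' @param regions named integer vector: units per region.
#' @param rate_range range of baseline firing rates in Hz.
#' @param n_latent number of latent behaviour factors.
#' @param latent_cutoff low-pass cutoff of the latent factors in Hz.
#' @param behavior_rate video frame rate in Hz.
#' @param n_behavior_components SVD components per behaviour stream.
#' @param coupling_depth linear modulation depth of unit rates by latents.
#' @param coupling_tuned amplitude of the bell-shaped (Gaussian) tuning of
#'   each unit to a preferred value of its latent projection — the
#'   non-monotone component a purely linear read-out cannot capture.
#' @param tuning_width width (sd) of the Gaussian tuning curve.
#' @param coupling_noise sd of extra rate noise (0 = rates are a deterministic
#'   function of the latents).
#' @param responsive_fraction fraction of units per region with laser-locked
#'   responses.
#' @param latency_range programmed response latency range in seconds.
#' @param region_latency_offset optional named vector of per-region latency
#'   shifts in seconds.
#' @param burst_rate,burst_duration onset burst: firing rate (Hz) and duration
#'   (s) of the pulse-locked volley beginning at the programmed latency.
#' @param sustained_excess,response_duration sustained rate excess (Hz) and its
#'   duration (s) after the burst.
#' @param laser_onsets,laser_duration,laser_hz laser schedule (onsets s,
#'   duration s, pulse frequency Hz per train).
#' @param syncope_delay_range uniform range of syncope delay after 20-Hz
#'   onset (s).
#' @param syncope_duration_range uniform range of bout duration (s).
#' @param power_drop fractional broadband (8-100 Hz) power loss during the
#'   bout (0.8 = power falls to 20% of baseline).
#' @param spike_suppression fraction of spikes removed from suppressed units
#'   during the bout (1 = complete silence; > 1 is rejected).
#' @param suppressed_regions regions whose units are suppressed at syncope
#'   (default: all but PVZ).
#' @param eeg_rate,ecg_rate,ldf_rate,piezo_rate stream sample rates in Hz.
#' @param hr_baseline_bpm,hr_min_frac,asystole_duration heart-rate profile:
#'   baseline bpm, minimum fraction reached during 20-Hz stimulation, and
#'   asystole length (s) at the heart-rate minimum.
#' @param ldf_min named vector of minimum normalized flow per pulse frequency.
#' @param rr_baseline_bpm baseline respiration rate (breaths/min).
#' @param streams which continuous channels to synthesize.
#' @return a `generator_config` list.
#' @export
generator_config <- function(
    duration = 600, seed = 1,
    regions = c(PVZ = 8L, SSp = 8L, BMA = 8L, HPC = 8L, ACA = 8L),
    rate_range = c(2, 8), n_latent = 5, latent_cutoff = 1,
    behavior_rate = 30, n_behavior_components = 250,
    coupling_depth = 0.6, coupling_tuned = 1.5, tuning_width = 0.4,
    coupling_noise = 0,
    responsive_fraction = 0.5, latency_range = c(0.01, 0.1),
    region_latency_offset = NULL,
    burst_rate = 500, burst_duration = 0.03,
    sustained_excess = 20, response_duration = 2,
    laser_onsets = c(66, 129, 192, 255), laser_duration = 30,
    laser_hz = c(5, 10, 20, 20),
    syncope_delay_range = c(4, 8), syncope_duration_range = c(10, 20),
    power_drop = 0.8, spike_suppression = 1, suppressed_regions = NULL,
    eeg_rate = 500, ecg_rate = 1000, ldf_rate = 100, piezo_rate = 100,
    hr_baseline_bpm = 600, hr_min_frac = 0.3, asystole_duration = 3,
    ldf_min = c(`5` = 0.85, `10` = 0.7, `20` = 0.4),
    rr_baseline_bpm = 180,
    streams = c("eeg", "ecg", "ldf", "piezo")) {
  cfg <- as.list(environment())
  if (cfg$spike_suppression > 1 || cfg$spike_suppression < 0)
    stop_validation("spike_suppression must lie in [0, 1]")
  if (cfg$power_drop < 0 || cfg$power_drop >= 1)
    stop_validation("power_drop must lie in [0, 1)")
  if (length(cfg$laser_hz) != length(cfg$laser_onsets))
    stop_validation("laser_hz and laser_onsets lengths differ")
  if (any(cfg$laser_onsets + cfg$laser_duration > cfg$duration))
    stop_validation("laser schedule exceeds session duration")
  if (is.null(cfg$suppressed_regions))
    cfg$suppressed_regions <- setdiff(names(cfg$regions), "PVZ")
  class(cfg) <- "generator_config"
  cfg
}

# 1/f ("pink") noise via FFT shaping, unit variance.
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  fx <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  shape <- 1 / sqrt(pmax(f, fs / n))
  x <- Re(stats::fft(fx * shape, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# Low-pass filtered white noise rows, standardized (the latent factors).
# Warm-up padding on both ends keeps the filter's edge transients out of the
# session, so early-session latents are as stationary as the rest.
smooth_latents <- function(n_latent, n_frames, fs, cutoff) {
  bt <- signal::butter(2, min(0.99, cutoff / (fs / 2)), type = "low")
  pad <- ceiling(4 * fs / cutoff)
  z <- matrix(0, n_latent, n_frames)
  for (i in seq_len(n_latent)) {
    v <- as.numeric(signal::filtfilt(bt, stats::rnorm(n_frames + 2 * pad)))
    v <- v[(pad + 1):(pad + n_frames)]
    z[i, ] <- (v - mean(v)) / stats::sd(v)
  }
  z
}

# Inhomogeneous Poisson spikes by thinning of rate_fun over [0, duration].
# rate_fun is vectorized; rate_max must bound it.
thin_poisson <- function(rate_fun, rate_max, duration) {
  n_cand <- stats::rpois(1, rate_max * duration)
  if (n_cand == 0L) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, duration))
  keep <- stats::runif(n_cand) < rate_fun(cand) / rate_max
  cand[keep]
}

#' Simulate spike trains with a programmed laser-locked step response
#'
#' Homogeneous Poisson baseline plus, after each onset and the programmed
#' latency, an onset burst (`burst_rate` for `burst_duration`) followed by a
#' sustained excess to `step_rate` for `response_duration`. With
#' `burst_rate = 0` the response is a pure rate step.
#'
#' @param base_rate baseline rate in Hz.
#' @param step_rate sustained rate during the response in Hz.
#' @param latency programmed latency in seconds.
#' @param onsets laser onset times in seconds.
#' @param extent recording extent `c(lo, hi)` in seconds.
#' @param response_duration sustained-response length in seconds.
#' @param burst_rate,burst_duration onset burst parameters (see
#'   [generator_config()]).
#' @return sorted spike time vector.
#' @export
simulate_step_train <- function(base_rate, step_rate, latency, onsets,
                                extent = c(0, 100), response_duration = 0.5,
                                burst_rate = 500, burst_duration = 0.03) {
  duration <- extent[2] - extent[1]
  base <- extent[1] + sort(stats::runif(stats::rpois(1, base_rate * duration),
                                        0, duration))
  extra <- unlist(lapply(onsets, function(on) {
    t0 <- on + latency
    b <- t0 + sort(stats::runif(stats::rpois(1, burst_rate * burst_duration),
                                0, burst_duration))
    s <- t0 + burst_duration +
      sort(stats::runif(stats::rpois(1, max(0, step_rate - base_rate) *
                                       response_duration),
                        0, response_duration))
    c(b, s)
  }))
  st <- sort(c(base, extra))
  st[st >= extent[1] & st <= extent[2]]
}

# Piecewise-linear profile evaluated on a grid: nodes (t, v), linear between.
profile_curve <- function(times, nodes) {
  stats::approx(nodes$t, nodes$v, xout = times, rule = 2)$y
}

#' Generate a complete synthetic session with ground truth
#'
#' See [generator_config()] for the programmed phenomena. All randomness is
#' fixed by `config$seed`; two calls with the same config are identical.
#'
#' @param config a [generator_config()].
#' @return list with `session` (a [session]) and `truth` (list: `syncope`
#'   table, `unit_latencies`, `responsive_units`, `suppressed_units`,
#'   `inactive_unit_ids`, `coupling` (weights/base/depth + latent matrix),
#'   `hr_profile`, `ldf_profile`, `rr_profile`, `blink_frames`,
#'   `expected_counts`, `lasers`).
#' @export
generate_session <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  dur <- cfg$duration
  fps <- cfg$behavior_rate
  n_frames <- round(dur * fps)
  frame_t <- (seq_len(n_frames) - 1) / fps

  lasers <- laser_events(cfg$laser_onsets, cfg$laser_duration, cfg$laser_hz)

  # --- programmed syncope bouts (one per 20-Hz train) ----------------------
  is20 <- lasers$pulse_hz == 20
  syncope <- NULL
  if (any(is20)) {
    on20 <- lasers$onset[is20]
    delay <- stats::runif(length(on20), cfg$syncope_delay_range[1],
                          cfg$syncope_delay_range[2])
    sdur <- stats::runif(length(on20), cfg$syncope_duration_range[1],
                         cfg$syncope_duration_range[2])
    syncope <- data.frame(laser_onset = on20, onset = on20 + delay,
                          offset = on20 + delay + sdur)
  }

  # --- behaviour latents and streams ---------------------------------------
  z <- smooth_latents(cfg$n_latent, n_frames, fps, cfg$latent_cutoff)
  ncomp <- cfg$n_behavior_components
  A_movie <- matrix(stats::rnorm(ncomp * cfg$n_latent), ncomp) / sqrt(cfg$n_latent)
  A_motion <- matrix(stats::rnorm(ncomp * cfg$n_latent), ncomp) / sqrt(cfg$n_latent)
  x_movie <- A_movie %*% z + 0.05 * matrix(stats::rnorm(ncomp * n_frames), ncomp)
  x_motion <- pmax(A_motion %*% z, 0) +
    0.05 * matrix(stats::rnorm(ncomp * n_frames), ncomp)
  B_whisk <- matrix(stats::rnorm(10 * cfg$n_latent), 10) / sqrt(cfg$n_latent)
  whisker <- B_whisk %*% z

  # --- units ---------------------------------------------------------------
  region_names <- rep(names(cfg$regions), cfg$regions)
  n_units <- length(region_names)
  unit_ids <- sprintf("u%03d", seq_len(n_units))
  base <- stats::runif(n_units, cfg$rate_range[1], cfg$rate_range[2])
  W <- matrix(stats::rnorm(n_units * cfg$n_latent), n_units)
  W <- W / sqrt(rowSums(W^2))
  V <- matrix(stats::rnorm(n_units * cfg$n_latent), n_units)
  V <- V / sqrt(rowSums(V^2))
  centers <- stats::rnorm(n_units)
  lin <- W %*% z
  # bell-shaped tuning to a per-unit preferred latent value, centred so the
  # expected gain under stationary latents stays 1
  w2 <- cfg$tuning_width^2
  bell <- exp(-(V %*% z - centers)^2 / (2 * w2))
  bell_mean <- sqrt(w2 / (1 + w2)) * exp(-centers^2 / (2 * (1 + w2)))
  gain <- 1 + cfg$coupling_depth * lin +
    cfg$coupling_tuned * (bell - bell_mean)
  if (cfg$coupling_noise > 0)
    gain <- gain + cfg$coupling_noise *
      matrix(stats::rnorm(n_units * n_frames), n_units)
  rate_behav <- pmax(base * gain, 0)   # units x frames, the coupled rates

  responsive <- unlist(lapply(split(seq_len(n_units), region_names), function(ix)
    sample(ix, round(cfg$responsive_fraction * length(ix)))))
  responsive <- sort(unname(responsive))
  lat_off <- rep(0, n_units)
  if (!is.null(cfg$region_latency_offset)) {
    ro <- cfg$region_latency_offset
    lat_off <- ifelse(region_names %in% names(ro), ro[region_names], 0)
  }
  unit_latencies <- rep(NA_real_, n_units)
  unit_latencies[responsive] <-
    stats::runif(length(responsive), cfg$latency_range[1], cfg$latency_range[2]) +
    lat_off[responsive]
  suppressed <- which(region_names %in% cfg$suppressed_regions)

  in_syncope <- function(t) {
    if (is.null(syncope)) return(rep(FALSE, length(t)))
    out <- rep(FALSE, length(t))
    for (i in seq_len(nrow(syncope)))
      out <- out | (t >= syncope$onset[i] & t < syncope$offset[i])
    out
  }

  units <- vector("list", n_units)
  expected_counts <- numeric(n_units)
  for (u in seq_len(n_units)) {
    rfun <- stats::approxfun(frame_t, rate_behav[u, ], rule = 2)
    rmax <- max(rate_behav[u, ]) * 1.001 + 1e-6
    st <- thin_poisson(rfun, rmax, dur)
    if (u %in% responsive) {
      lat <- unit_latencies[u]
      for (li in seq_len(nrow(lasers))) {
        t0 <- lasers$onset[li] + lat
        nb <- stats::rpois(1, cfg$burst_rate * cfg$burst_duration)
        ns <- stats::rpois(1, cfg$sustained_excess * cfg$response_duration)
        st <- c(st,
                t0 + stats::runif(nb, 0, cfg$burst_duration),
                t0 + cfg$burst_duration +
                  stats::runif(ns, 0, cfg$response_duration))
      }
    }
    st <- sort(st[st >= 0 & st <= dur])
    if (u %in% suppressed && cfg$spike_suppression > 0 && !is.null(syncope)) {
      drop <- in_syncope(st) & stats::runif(length(st)) <= cfg$spike_suppression
      st <- st[!drop]
    }
    st <- unique(st)
    # lambda excluding the encoding test windows (-3 .. +60 s around onsets)
    test_mask_len <- 0
    in_test <- rep(FALSE, length(st))
    for (on in lasers$onset) {
      lo <- max(0, on - 3); hi <- min(dur, on + 60)
      test_mask_len <- test_mask_len + (hi - lo)
      in_test <- in_test | (st >= lo & st < hi)
    }
    lam <- sum(!in_test) / max(dur - test_mask_len, 1e-9)
    units[[u]] <- spike_train(unit_ids[u], region_names[u], st,
                              baseline_rate = lam)
    # expected count from the programmed rate (for the Poisson count check)
    exp_behav <- sum(rate_behav[u, ]) / fps
    exp_resp <- if (u %in% responsive)
      nrow(lasers) * (cfg$burst_rate * cfg$burst_duration +
                        cfg$sustained_excess * cfg$response_duration) else 0
    exp_supp <- if (u %in% suppressed && !is.null(syncope))
      cfg$spike_suppression *
        sum(rate_behav[u, in_syncope(frame_t)]) / fps else 0
    expected_counts[u] <- exp_behav + exp_resp - exp_supp
  }

  # --- EEG: 1/f noise with multiplicative 8-100 Hz suppression -------------
  streams <- list()
  if ("eeg" %in% cfg$streams) {
    fs <- cfg$eeg_rate
    n <- round(dur * fs)
    x <- pink_noise(n, fs)
    # exact spectral split so the suppressed band carries *all* 8-100 Hz power
    fx <- stats::fft(x)
    f <- (0:(n - 1)) * fs / n
    f[f > fs / 2] <- fs - f[f > fs / 2]
    m <- f >= 8 & f <= 100
    band <- Re(stats::fft(fx * m, inverse = TRUE)) / n
    rest <- x - band
    env <- rep(1, n)
    amp <- sqrt(1 - cfg$power_drop)
    if (!is.null(syncope)) {
      tt <- (seq_len(n) - 1) / fs
      ramp <- 0.5
      for (i in seq_len(nrow(syncope))) {
        s <- syncope$onset[i]; e <- syncope$offset[i]
        env <- env * ifelse(
          tt < s - ramp / 2 | tt > e + ramp / 2, 1,
          ifelse(tt < s + ramp / 2,
                 1 - (1 - amp) * (tt - (s - ramp / 2)) / ramp,
                 ifelse(tt > e - ramp / 2,
                        amp + (1 - amp) * (tt - (e - ramp / 2)) / ramp,
                        amp)))
      }
    }
    streams$eeg <- time_series(rest + env * band, fs, label = "eeg")
  }

  # --- ECG: R-peak impulse train following the heart-rate profile ----------
  hr_nodes <- data.frame(t = 0, v = cfg$hr_baseline_bpm)
  add_node <- function(nodes, t, v) rbind(nodes, data.frame(t = t, v = v))
  for (li in seq_len(nrow(lasers))) {
    on <- lasers$onset[li]; hz <- lasers$pulse_hz[li]
    end <- on + lasers$duration[li]
    if (hz == 20 && !is.null(syncope)) {
      srow <- syncope[syncope$laser_onset == on, ][1, ]
      # event order: asystole (HR minimum), then the flow minimum, then the
      # 50% power drop at srow$onset
      asys0 <- srow$onset - 1 - cfg$asystole_duration
      hr_nodes <- add_node(hr_nodes, on, cfg$hr_baseline_bpm)
      hr_nodes <- add_node(hr_nodes, asys0 - 0.5,
                           cfg$hr_baseline_bpm * cfg$hr_min_frac)
      hr_nodes <- add_node(hr_nodes, asys0, 0)    # asystole
      hr_nodes <- add_node(hr_nodes, asys0 + cfg$asystole_duration, 0)
      hr_nodes <- add_node(hr_nodes, asys0 + cfg$asystole_duration + 0.5,
                           cfg$hr_baseline_bpm * cfg$hr_min_frac)
      hr_nodes <- add_node(hr_nodes, end + 20, cfg$hr_baseline_bpm)
    } else {
      frac <- if (hz <= 5) 0.85 else 0.6
      hr_nodes <- add_node(hr_nodes, on, cfg$hr_baseline_bpm)
      hr_nodes <- add_node(hr_nodes, on + lasers$duration[li] / 2,
                           cfg$hr_baseline_bpm * frac)
      hr_nodes <- add_node(hr_nodes, end + 10, cfg$hr_baseline_bpm)
    }
  }
  hr_nodes <- add_node(hr_nodes, dur, cfg$hr_baseline_bpm)
  hr_nodes <- hr_nodes[order(hr_nodes$t), ]
  hr_grid_t <- seq(0, dur, by = 0.01)
  hr_bpm <- profile_curve(hr_grid_t, hr_nodes)
  if ("ecg" %in% cfg$streams) {
    fs <- cfg$ecg_rate
    n <- round(dur * fs)
    beats <- cumsum(hr_bpm / 60 * 0.01)
    beat_t <- hr_grid_t[c(FALSE, diff(floor(beats)) >= 1)]
    ecg <- 0.01 * stats::rnorm(n)
    tt_idx <- round(beat_t * fs) + 1
    sigma <- 0.0025 * fs                       # 10-ms wide Gaussian R peak
    half <- ceiling(4 * sigma)
    bump <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    for (bi in tt_idx) {
      lo <- max(1, bi - half); hi <- min(n, bi + half)
      ecg[lo:hi] <- ecg[lo:hi] + bump[(lo - bi + half + 1):(hi - bi + half + 1)]
    }
    streams$ecg <- time_series(ecg, fs, label = "ecg")
  }

  # --- LDF: stimulus-locked flow dip ---------------------------------------
  ldf_nodes <- data.frame(t = 0, v = 1)
  for (li in seq_len(nrow(lasers))) {
    on <- lasers$onset[li]; hz <- lasers$pulse_hz[li]
    end <- on + lasers$duration[li]
    vmin <- cfg$ldf_min[as.character(hz)]
    if (is.na(vmin)) vmin <- 0.9
    if (hz == 20 && !is.null(syncope)) {
      srow <- syncope[syncope$laser_onset == on, ][1, ]
      tmin <- srow$onset - 0.5                   # flow minimum after HR minimum,
      ldf_nodes <- add_node(ldf_nodes, on + 0.2, 1)  # before the power drop
      ldf_nodes <- add_node(ldf_nodes, tmin, vmin)
      ldf_nodes <- add_node(ldf_nodes, end, vmin + 0.1)
      ldf_nodes <- add_node(ldf_nodes, end + 15, 1)
    } else {
      ldf_nodes <- add_node(ldf_nodes, on + 0.2, 1)
      ldf_nodes <- add_node(ldf_nodes, on + lasers$duration[li] / 2, vmin)
      ldf_nodes <- add_node(ldf_nodes, end + 10, 1)
    }
  }
  ldf_nodes <- add_node(ldf_nodes, dur, 1)
  ldf_nodes <- ldf_nodes[order(ldf_nodes$t), ]
  if ("ldf" %in% cfg$streams) {
    fs <- cfg$ldf_rate
    tt <- (seq_len(round(dur * fs)) - 1) / fs
    ldf <- profile_curve(tt, ldf_nodes) + 0.01 * stats::rnorm(length(tt))
    streams$ldf <- time_series(ldf, fs, label = "ldf")
  }

  # --- respiration piezo: frequency-modulated breathing --------------------
  rr_nodes <- data.frame(t = 0, v = cfg$rr_baseline_bpm)
  for (li in seq_len(nrow(lasers))) {
    on <- lasers$onset[li]; hz <- lasers$pulse_hz[li]
    end <- on + lasers$duration[li]
    frac <- if (hz == 20) 0.5 else 0.85
    rr_nodes <- add_node(rr_nodes, on, cfg$rr_baseline_bpm)
    rr_nodes <- add_node(rr_nodes, on + 5, cfg$rr_baseline_bpm * frac)
    rr_nodes <- add_node(rr_nodes, end, cfg$rr_baseline_bpm * frac)
    rr_nodes <- add_node(rr_nodes, end + 10, cfg$rr_baseline_bpm)
  }
  rr_nodes <- add_node(rr_nodes, dur, cfg$rr_baseline_bpm)
  rr_nodes <- rr_nodes[order(rr_nodes$t), ]
  if ("piezo" %in% cfg$streams) {
    fs <- cfg$piezo_rate
    tt <- (seq_len(round(dur * fs)) - 1) / fs
    rr <- profile_curve(tt, rr_nodes)
    phase <- cumsum(2 * pi * rr / 60 / fs)
    streams$piezo <- time_series(sin(phase) + 0.05 * stats::rnorm(length(tt)),
                                 fs, label = "piezo")
  }

  # --- pupil keypoints, blinks ---------------------------------------------
  r0 <- 10; gdil <- 1.5
  radius <- rep(r0, n_frames)
  for (on in lasers$onset) {
    ramp_up <- frame_t >= on & frame_t < on + 2
    hold <- frame_t >= on + 2 & frame_t < on + 7
    decay <- frame_t >= on + 7 & frame_t < on + 17
    radius[ramp_up] <- r0 * (1 + (gdil - 1) * (frame_t[ramp_up] - on) / 2)
    radius[hold] <- r0 * gdil
    radius[decay] <- r0 * (gdil - (gdil - 1) * (frame_t[decay] - on - 7) / 10)
  }
  blink_starts <- sort(stats::runif(3, 5, min(60, dur) - 5))
  blink <- rep(FALSE, n_frames)
  for (b in blink_starts) blink <- blink | (frame_t >= b & frame_t < b + 0.2)
  cx <- 50; cy <- 50
  kp <- array(0, dim = c(4, 2, n_frames),
              dimnames = list(c("top", "bottom", "left", "right"),
                              c("x", "y"), NULL))
  jit <- function() 0.02 * stats::rnorm(n_frames)
  kp[1, 1, ] <- cx + jit();          kp[1, 2, ] <- cy + radius + jit()
  kp[2, 1, ] <- cx + jit();          kp[2, 2, ] <- cy - radius + jit()
  kp[3, 1, ] <- cx - radius + jit(); kp[3, 2, ] <- cy + jit()
  kp[4, 1, ] <- cx + radius + jit(); kp[4, 2, ] <- cy + jit()
  conf <- matrix(0.98, 4, n_frames)
  conf[, blink] <- 0.3
  eye_dark <- round(400 + 5 * stats::rnorm(n_frames))
  eye_dark[blink] <- round(50 + 5 * stats::rnorm(sum(blink)))

  behavior <- behavior_streams(
    x_movie = x_movie, x_motion = x_motion, whisker_motion_svd = whisker,
    keypoints = kp, confidence = conf, eye_dark_pixel_count = eye_dark,
    sample_rate = fps)

  ses <- session(sprintf("synthetic-%d", cfg$seed), streams = streams,
                 units = units, behavior = behavior, lasers = lasers,
                 metadata = list(generator = "synckit", seed = cfg$seed))
  truth <- list(
    syncope = syncope,
    unit_latencies = stats::setNames(unit_latencies, unit_ids),
    responsive_units = unit_ids[responsive],
    suppressed_units = unit_ids[suppressed],
    inactive_unit_ids = unit_ids[suppressed],
    coupling = list(weights = W, tuning_weights = V,
                    tuning_centers = centers, base = base,
                    depth = cfg$coupling_depth, tuned = cfg$coupling_tuned,
                    tuning_width = cfg$tuning_width,
                    latents = z, rate_behav = rate_behav),
    hr_profile = data.frame(t = hr_grid_t, bpm = hr_bpm),
    ldf_profile = ldf_nodes,
    rr_profile = rr_nodes,
    blink_frames = which(blink),
    expected_counts = stats::setNames(expected_counts, unit_ids),
    lasers = lasers,
    pupil = list(radius = radius, dilation = gdil))
  list(session = ses, truth = truth)
}

#' Write the ground truth of a synthetic session as JSON
#'
#' Scalar/tabular truth only (matrices such as the latent factors stay in
#' memory); the file sits next to the bundle as `<id>.truth.json`.
#'
#' @param truth the `truth` element of [generate_session()].
#' @param path output file.
#' @export
save_ground_truth <- function(truth, path) {
  keep <- truth[c("syncope", "unit_latencies", "responsive_units",
                  "suppressed_units", "inactive_unit_ids", "hr_profile",
                  "ldf_profile", "rr_profile", "blink_frames",
                  "expected_counts", "lasers")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Small deterministic worked fixtures used by the unit tests.
# ---------------------------------------------------------------------------

#' @rdname generate_worked_fixtures
#' @export
fixture_sinusoid <- function(freq = 40, duration = 10, fs = 500, amp = 1) {
  tt <- (seq_len(round(duration * fs)) - 1) / fs
  time_series(amp * sin(2 * pi * freq * tt), fs, label = "sinusoid")
}

#' @rdname generate_worked_fixtures
#' @export
fixture_triangle_ldf <- function(fs = 20, baseline = 30, dip_start = 30,
                                 slope = 0.1, half_width = 5, total = 190) {
  tt <- (seq_len(round(total * fs)) - 1) / fs
  v <- rep(1, length(tt))
  down <- tt >= dip_start & tt < dip_start + half_width
  up <- tt >= dip_start + half_width & tt < dip_start + 2 * half_width
  v[down] <- 1 - slope * (tt[down] - dip_start)
  v[up] <- 1 - slope * half_width + slope * (tt[up] - dip_start - half_width)
  time_series(v, fs, label = "ldf")
}

#' @rdname generate_worked_fixtures
#' @export
fixture_impulse_ecg <- function(rr = 0.15, duration = 120, fs = 500) {
  n <- round(duration * fs)
  ecg <- numeric(n)
  peaks <- seq(rr, duration - rr, by = rr)
  sigma <- 0.0025 * fs
  half <- ceiling(4 * sigma)
  bump <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  for (p in round(peaks * fs) + 1) {
    lo <- max(1, p - half); hi <- min(n, p + half)
    ecg[lo:hi] <- ecg[lo:hi] + bump[(lo - p + half + 1):(hi - p + half + 1)]
  }
  time_series(ecg, fs, label = "ecg")
}

#' @rdname generate_worked_fixtures
#' @export
fixture_pupil_circle <- function(radius = 1, n_frames = 30, center = c(0, 0)) {
  kp <- array(0, dim = c(4, 2, n_frames),
              dimnames = list(c("top", "bottom", "left", "right"),
                              c("x", "y"), NULL))
  kp[1, 1, ] <- center[1]; kp[1, 2, ] <- center[2] + radius
  kp[2, 1, ] <- center[1]; kp[2, 2, ] <- center[2] - radius
  kp[3, 1, ] <- center[1] - radius; kp[3, 2, ] <- center[2]
  kp[4, 1, ] <- center[1] + radius; kp[4, 2, ] <- center[2]
  kp
}

#' @rdname generate_worked_fixtures
#' @export
fixture_step_lfp <- function(duration = 30, fs = 500, step_window = c(10, 20),
                             step_amp = 0.3, seed = 42) {
  set.seed(seed)
  tt <- (seq_len(round(duration * fs)) - 1) / fs
  x <- stats::rnorm(length(tt))
  x[tt >= step_window[1] & tt < step_window[2]] <-
    step_amp * x[tt >= step_window[1] & tt < step_window[2]]
  time_series(x, fs, label = "lfp")
}

#' Write the deterministic worked fixtures as CSV files
#'
#' Small analytic traces used throughout the unit tests: a 40-Hz sinusoid, a
#' symmetric triangular flow dip, an R-peak impulse train at 400 bpm, a
#' four-keypoint pupil circle, and a broadband trace whose amplitude steps to
#' 0.3x during 10-20 s.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
generate_worked_fixtures <- function(dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writers <- list(
    sinusoid_40hz = fixture_sinusoid(),
    triangle_ldf = fixture_triangle_ldf(),
    impulse_ecg = fixture_impulse_ecg(),
    step_lfp = fixture_step_lfp())
  files <- character(0)
  for (nm in names(writers)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    s <- writers[[nm]]
    data.table::fwrite(data.table::data.table(
      time_s = ts_times(s), value = s$values), f)
    files[nm] <- f
  }
  kp <- fixture_pupil_circle()
  f <- file.path(dir, "pupil_circle.csv")
  long <- data.table::data.table(
    frame = rep(seq_len(dim(kp)[3]), each = 4L),
    point = rep(rownames(kp), dim(kp)[3]),
    x = as.vector(kp[, 1, ]), y = as.vector(kp[, 2, ]))
  data.table::fwrite(long, f)
  files["pupil_circle"] <- f
  files
}
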