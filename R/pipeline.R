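# End-to-end orchestration: spectral -> syncope events -> spikes/encoding ->
# physiology, mirroring the analysis dependencies (activation classification
# consumes encoding residuals; syncope-aligned statistics consume the
# spectral stage's events).

#' Run the full analysis pipeline on one session
#'
#' Stage order: spectral (wavelet spectrograms per laser window, syncope
#' detection on 20-Hz trials), spike curation and Poisson statistics,
#' behaviour encoding with nearest-neighbour residuals, unit activation
#' classification, physiology (heart rate, respiration, LDF metrics, event
#' sequence), and per-region summaries. A disabled or failed stage skips its
#' dependents with an explicit note; independent stages still run.
#'
#' @param ses a [session] or a bundle path for [load_session()].
#' @param config a [default_config()] (stage parameters and enable flags).
#' @param output_dir optional directory: numeric tables are written as CSV.
#' @return a `pipeline_report` list: `syncope`, `spectrograms`,
#'   `unit_table`, `region_table`, `encoding`, `physiology`, `notes`
#'   (skip/dependency messages), `config`.
#' @export
run_pipeline <- function(ses, config = default_config(), output_dir = NULL) {
  if (is.character(ses)) ses <- load_session(ses)
  stopifnot(inherits(ses, "session"))
  notes <- character(0)
  note <- function(...) notes <<- c(notes, paste0(...))
  report <- list(config = config)
  duration <- max(c(vapply(ses$streams, function(s) s$t0 + ts_duration(s),
                           numeric(1)),
                    if (!is.null(ses$behavior))
                      ncol(ses$behavior$x_movie) / ses$behavior$sample_rate))

  # ---- spectral ------------------------------------------------------------
  syncope <- NULL
  spectrograms <- list()
  if (isTRUE(config$stages$spectral)) {
    sp <- config$spectral
    stream <- ses$streams[[sp$stream]]
    if (is.null(stream)) {
      note("spectral: stream '", sp$stream, "' missing; stage skipped")
    } else if (is.null(ses$lasers) || !nrow(ses$lasers)) {
      note("spectral: no laser events; stage skipped")
    } else {
      filtered <- notch_filter(stream, sp$notch)
      freqs <- wavelet_freqs(sp$n_wavelets, sp$fmin, sp$fmax)
      dec <- max(1L, round(stream$sample_rate / sp$target_rate))
      syn_rows <- list()
      for (li in seq_len(nrow(ses$lasers))) {
        on <- ses$lasers$onset[li]
        w0 <- max(stream$t0, on - sp$baseline_pre)
        w1 <- min(stream$t0 + ts_duration(stream),
                  on + ses$lasers$duration[li] + sp$window_post)
        seg <- ts_window(filtered, w0, w1)
        spec <- wavelet_power(seg, analysis_window(w0, on, "baseline"),
                              freqs = freqs, gamma = sp$gamma, beta = sp$beta,
                              time_decimate = dec)
        spectrograms[[li]] <- spec
        if (ses$lasers$pulse_hz[li] == 20) {
          ev <- detect_syncope(spec, laser_onset = on, band = sp$band,
                               onset_frac = sp$onset_frac,
                               offset_frac = sp$offset_frac,
                               smooth_window = sp$smooth_window)
          if (!is.null(ev)) syn_rows[[length(syn_rows) + 1L]] <- ev
        }
      }
      if (length(syn_rows)) {
        syncope <- do.call(rbind, syn_rows)
        syncope$laser_onset <- syncope$laser_onset
      } else note("spectral: no syncope bout detected")
    }
  } else note("spectral: disabled")
  report$syncope <- syncope
  report$spectrograms <- spectrograms

  # ---- encoding ------------------------------------------------------------
  enc <- NULL
  if (isTRUE(config$stages$encoding)) {
    if (is.null(ses$behavior)) {
      note("encoding: no behaviour streams; stage skipped")
    } else if (!length(ses$units)) {
      note("encoding: no units; stage skipped")
    } else {
      ec <- config$encoding
      spec <- encoder_spec(hidden = ec$hidden, conv_channels = ec$conv_channels,
                           kernel = ec$kernel, latent = ec$latent, lr = ec$lr,
                           weight_decay = ec$weight_decay,
                           max_epochs = ec$max_epochs, patience = ec$patience)
      enc <- encode_session(ses, spec = spec, k = ec$k_neighbours,
                            seed = config$seed, syncope = syncope)
    }
  } else note("encoding: disabled")
  report$encoding <- enc

  # ---- spikes --------------------------------------------------------------
  unit_table <- NULL
  if (isTRUE(config$stages$spikes) && length(ses$units)) {
    sk <- config$spikes
    drift <- flag_drifting_units(ses$units, duration, sk$drift_bin,
                                 sk$drift_sigma, sk$drift_factor, sk$drift_eps)
    low <- flag_low_rate_units(ses$units, duration, sk$low_rate_threshold)
    lam <- baseline_rates(ses$units, duration, ses$lasers)
    onsets <- if (!is.null(ses$lasers)) ses$lasers$onset else numeric(0)
    rows <- lapply(seq_along(ses$units), function(u) {
      un <- ses$units[[u]]
      un$baseline_rate <- lam[u]
      curated <- !isTRUE(drift[u]) && !low[u]
      lat <- if (curated && length(onsets) && lam[u] > 0)
        laser_latency(un, onsets, sk$p_threshold, sk$latency_step,
                      sk$latency_max) else NA_real_
      inact <- NA
      toff <- NA_real_
      kk <- NA_integer_
      if (curated && !is.null(syncope) && nrow(syncope) && lam[u] > 0) {
        per_ev <- lapply(seq_len(nrow(syncope)), function(i) {
          le <- syncope$laser_onset[i]
          li <- if (length(onsets)) which.min(abs(onsets - le)) else NA
          wend <- if (!is.na(li))
            onsets[li] + ses$lasers$duration[li] else syncope$onset[i] + 4
          inactive_at_syncope(
            un, syncope[i, ],
            list(P0 = sk$P0, dt = sk$dt, k_max = sk$k_max,
                 onset_tolerance = sk$onset_tolerance),
            extent = c(0, duration), window_end = wend)
        })
        fl <- vapply(per_ev, `[[`, logical(1), "inactive")
        inact <- mean(fl) >= 0.5
        kk <- per_ev[[1]]$k
        toff <- if (any(fl))
          mean(vapply(per_ev[fl], `[[`, numeric(1), "time_off")) else NA_real_
      }
      c1 <- c2 <- c3 <- act <- NA
      if (curated && !is.null(enc) && length(onsets)) {
        cl <- classify_laser_activated(
          enc$result$residual[u, ], enc$bin_times, onsets, lat,
          sk$onset_window, sk$pre_window, sk$activation_latency_max)
        c1 <- cl$criterion1; c2 <- cl$criterion2; c3 <- cl$criterion3
        act <- cl$activated
      } else if (curated && is.null(enc)) {
        note("classification: unit ", un$unit_id,
             " skipped (missing dependency: encoding residuals)")
      }
      data.frame(unit_id = un$unit_id, region = un$region,
                 drift_flag = drift[u], low_rate_flag = low[u],
                 lambda = lam[u], k_bins = kk,
                 inactive_at_syncope = inact, time_off = toff,
                 latency = lat, criterion1 = c1, criterion2 = c2,
                 criterion3 = c3, laser_activated = act)
    })
    unit_table <- do.call(rbind, rows)
    if (is.null(syncope))
      note("spikes: syncope statistics skipped (missing dependency: ",
           "spectral syncope events)")
  } else if (isTRUE(config$stages$spikes)) {
    note("spikes: no units; stage skipped")
  } else note("spikes: disabled")
  report$unit_table <- unit_table
  report$region_table <- if (!is.null(unit_table)) region_summary(unit_table)

  # ---- physiology ----------------------------------------------------------
  physio <- NULL
  if (isTRUE(config$stages$physiology) && !is.null(ses$lasers) &&
      nrow(ses$lasers)) {
    ph <- config$physiology
    physio <- list()
    if (!is.null(ses$streams$ecg)) {
      hr <- heart_rate(ses$streams$ecg, ph$ecg_band, ph$smooth_window)
      segs <- normalize_rate_trace(hr, ses$lasers, ph$baseline)
      physio$hr <- hr
      physio$hr_stats <- do.call(rbind, lapply(seq_along(segs), function(i) {
        st <- stim_window_stats(segs[[i]], "hr", ph$hr_stim_window,
                                ph$hr_post_window)
        data.frame(laser = i, onset = ses$lasers$onset[i],
                   stim = st$stim, post = st$post)
      }))
    } else note("physiology: no ECG stream")
    if (!is.null(ses$streams$piezo)) {
      rr <- respiration_rate(ses$streams$piezo, ph$resp_band, ph$smooth_window)
      if (length(rr$peak_times)) {
        segs <- normalize_rate_trace(rr, ses$lasers, ph$baseline)
        physio$rr <- rr
        physio$rr_stats <- do.call(rbind, lapply(seq_along(segs), function(i) {
          st <- stim_window_stats(segs[[i]], "rr", ph$rr_stim_window,
                                  ph$rr_post_window)
          data.frame(laser = i, onset = ses$lasers$onset[i],
                     stim = st$stim, post = st$post)
        }))
      }
    }
    if (!is.null(ses$streams$ldf)) {
      physio$ldf <- lapply(seq_len(nrow(ses$lasers)), function(i)
        ldf_metrics(ses$streams$ldf, ses$lasers$onset[i],
                    ses$lasers$duration[i], ph$ldf_baseline,
                    ph$ldf_median_window))
      physio$ldf_table <- do.call(rbind, lapply(seq_along(physio$ldf),
        function(i) {
          m <- physio$ldf[[i]]
          data.frame(laser = i, onset = ses$lasers$onset[i],
                     latency_50 = m$latency_50,
                     min_during_stim = m$min_during_stim,
                     fwhm_transit = m$fwhm_transit, late_mean = m$late_mean,
                     recovery_duration = m$recovery_duration,
                     rate_coefficient = m$rate_coefficient)
        }))
    }
    if (!is.null(syncope) && !is.null(ses$streams$ldf)) {
      physio$event_sequence <- syncope_event_sequence(
        hr = physio$hr, ldf = ses$streams$ldf, syncope = syncope,
        lasers = ses$lasers)
    } else if (is.null(syncope)) {
      note("physiology: syncope alignment skipped (missing dependency: ",
           "spectral syncope events)")
    }
  } else if (isTRUE(config$stages$physiology)) {
    note("physiology: no laser events; stage skipped")
  } else note("physiology: disabled")
  report$physiology <- physio
  report$notes <- notes
  class(report) <- "pipeline_report"

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, nm) if (!is.null(x))
      data.table::fwrite(data.table::as.data.table(x),
                         file.path(output_dir, nm))
    wr(report$syncope, "syncope.csv")
    wr(report$unit_table, "units.csv")
    wr(report$region_table, "regions.csv")
    if (!is.null(physio)) {
      wr(physio$hr_stats, "hr_stats.csv")
      wr(physio$rr_stats, "rr_stats.csv")
      wr(physio$ldf_table, "ldf_metrics.csv")
      wr(physio$event_sequence, "event_sequence.csv")
    }
    if (!is.null(enc)) wr(enc$result$summaries, "residual_summaries.csv")
    write_config(config, file.path(output_dir, "config.yaml"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  syncope events:", if (is.null(x$syncope)) 0 else nrow(x$syncope), "\n")
  cat("  units:", if (is.null(x$unit_table)) 0 else nrow(x$unit_table), "\n")
  if (length(x$notes)) cat("  notes:\n", paste0("   - ", x$notes, "\n"))
  invisible(x)
}

# Mean firing rate excluding the encoding test windows (-test_pre .. +60 s
# around each laser onset) -- the lambda of the Poisson statistics.
baseline_rates <- function(units, duration, lasers, test_pre = 3,
                           test_post = 60) {
  onsets <- if (!is.null(lasers)) lasers$onset else numeric(0)
  vapply(units, function(u) {
    st <- u$spike_times
    keep <- rep(TRUE, length(st))
    masked <- 0
    for (on in onsets) {
      lo <- max(0, on - test_pre); hi <- min(duration, on + test_post)
      keep <- keep & !(st >= lo & st < hi)
      masked <- masked + (hi - lo)
    }
    sum(keep) / max(duration - masked, 1e-9)
  }, numeric(1))
}

#' Run the synthetic recovery/validation suite
#'
#' Executes scaled-down versions of the generator-based recovery experiments
#' (syncope-onset detection, laser-latency estimation, Poisson inactivity
#' sensitivity and false-flag rate) across the given seeds and reports a
#' machine-readable pass/fail table. The full-scale versions live in the
#' package's acceptance tests.
#'
#' @param seeds integer vector of seeds (non-empty).
#' @return `data.frame`: `check`, `value`, `threshold`, `comparison`, `pass`.
#' @export
run_validation_suite <- function(seeds = 0:4) {
  if (!length(seeds)) stop_validation("seed list must be non-empty")
  onset_err <- c()
  for (s in seeds) {
    cfg <- generator_config(duration = 160, seed = s,
                            regions = c(PVZ = 2L, SSp = 2L),
                            laser_onsets = 70, laser_hz = 20,
                            laser_duration = 30, streams = "eeg")
    g <- generate_session(cfg)
    sp <- wavelet_power(
      notch_filter(g$session$streams$eeg),
      analysis_window(40, 70, "baseline"), time_decimate = 10)
    ev <- detect_syncope(sp, laser_onset = 70)
    onset_err <- c(onset_err,
                   if (is.null(ev)) NA_real_ else
                     abs(ev$onset - g$truth$syncope$onset[1]))
  }
  lat_err <- c()
  for (s in seeds) {
    set.seed(s + 1000)
    st <- simulate_step_train(5, 50, 0.05, c(100, 200, 300, 400),
                              extent = c(0, 500))
    u <- spike_train("sim", "SSp", unique(st), baseline_rate = 5)
    est <- laser_latency(u, c(100, 200, 300, 400))
    lat_err <- c(lat_err, abs(est - 0.05))
  }
  set.seed(7)
  sens <- fp <- c()
  for (s in seeds) {
    set.seed(s + 2000)
    lam <- stats::runif(10, 2, 8)
    syn <- data.frame(onset = 50, offset = 60)
    for (l in lam) {
      st_sup <- unique(sort(stats::runif(stats::rpois(1, l * 50), 0, 50)))  # silent after 50 s
      u <- spike_train("s", "SSp", st_sup, baseline_rate = l)
      sens <- c(sens, inactive_at_syncope(u, syn, extent = c(0, 100),
                                          window_end = 60)$inactive)
      st_nul <- sort(stats::runif(stats::rpois(1, l * 100), 0, 100))
      u2 <- spike_train("n", "SSp", unique(st_nul), baseline_rate = l)
      fp <- c(fp, inactive_at_syncope(u2, syn, extent = c(0, 100),
                                      window_end = 60)$inactive)
    }
  }
  out <- data.frame(
    check = c("syncope_onset_mae_s", "syncope_detected_fraction",
              "latency_mae_s", "inactivity_sensitivity",
              "inactivity_false_flag_rate"),
    value = c(mean(onset_err, na.rm = TRUE), mean(!is.na(onset_err)),
              stats::median(lat_err, na.rm = TRUE), mean(sens), mean(fp)),
    threshold = c(0.5, 0.9, 0.01, 0.9, 0.05),
    comparison = c("<=", ">=", "<=", ">=", "<="))
  out$pass <- ifelse(out$comparison == "<=", out$value <= out$threshold,
                     out$value >= out$threshold)
  out
}
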