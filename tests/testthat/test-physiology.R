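# ECG heart rate, respiration rate, adaptation subtraction, LDF metrics,
# and syncope alignment.

test_that("an impulse train every 150 ms reads as 400 bpm, baseline 1", {
  ecg <- fixture_impulse_ecg(rr = 0.15, duration = 120)
  hr <- heart_rate(ecg)
  tt <- ts_times(hr$bpm)
  interior <- tt > 5 & tt < 115
  expect_equal(mean(hr$bpm$values[interior]), 400, tolerance = 0.01)
  expect_lt(stats::sd(hr$bpm$values[interior]), 1)
  segs <- normalize_rate_trace(hr, laser_events(60, 30), post = 20)
  expect_equal(mean(segs[[1]]$values), 1, tolerance = 1e-3)
})

test_that("heart rate is invariant to ECG amplitude rescaling", {
  ecg <- fixture_impulse_ecg()
  big <- ecg; big$values <- 37 * ecg$values
  expect_equal(heart_rate(big)$peak_times, heart_rate(ecg)$peak_times)
})

test_that("programmed bradycardia and asystole are recovered from synthetic ECG", {
  g <- generate_session(tiny_generator_config(seed = 17))
  hr <- heart_rate(g$session$streams$ecg)
  segs <- normalize_rate_trace(hr, g$session$lasers, post = 30)
  # the asystole drives the smoothed normalized rate far below the
  # bradycardia plateau of 0.3
  expect_lt(min(segs[[1]]$values), 0.15)
  # the asystole shows up as the longest R-R interval
  longest <- max(diff(hr$peak_times))
  expect_equal(longest, tiny_generator_config()$asystole_duration,
               tolerance = 0.5)
  # bradycardia bottoms out after laser onset, not before
  seg <- segs[[1]]
  expect_gt(ts_times(seg)[which.min(seg$values)], 0)
})

test_that("respiration rate reads a 3-Hz sinusoid as 180 breaths/min", {
  tt <- seq(0, 60, by = 1 / 100)
  rr <- respiration_rate(time_series(sin(2 * pi * 3 * tt), 100))
  mid <- ts_times(rr$bpm) > 5 & ts_times(rr$bpm) < 55
  expect_equal(mean(rr$bpm$values[mid]), 180, tolerance = 1)
  # constant signal: no breaths, reported missing
  flat <- respiration_rate(time_series(rep(1, 3000), 100))
  expect_true(all(is.na(flat$bpm$values)))
  expect_length(flat$peak_times, 0)
})

test_that("shifted self-subtraction cancels periodicity and keeps transients", {
  fs <- 50
  tt <- seq(0, 100 - 1 / fs, by = 1 / fs)
  per <- time_series(sin(2 * pi * tt / 10), fs)       # period = shift = 10 s
  out <- adaptation_subtract(per, 10)
  expect_lt(max(abs(out$values)), 1e-10)
  expect_equal(out$t0, 10)
  const <- adaptation_subtract(time_series(rep(3, 5000), fs), 10)
  expect_true(all(const$values == 0))
  # linearity
  a <- time_series(rnorm(5000), fs)
  b <- time_series(rnorm(5000), fs)
  ab <- time_series(a$values + b$values, fs)
  expect_equal(adaptation_subtract(ab, 7)$values,
               adaptation_subtract(a, 7)$values +
                 adaptation_subtract(b, 7)$values, tolerance = 1e-12)
  # periodic dips + one drug transient: transient survives
  dips <- sin(2 * pi * tt / 10)
  trans <- exp(-(tt - 55)^2 / 8)
  mix <- time_series(dips + trans, fs)
  iso <- adaptation_subtract(mix, 10)
  t_iso <- ts_times(iso)
  expect_equal(t_iso[which.max(iso$values)], 55, tolerance = 1)
  expect_error(adaptation_subtract(per, 200), "exceeds")
  expect_error(adaptation_subtract(per, 0), "> 0")
})

test_that("the symmetric triangular dip yields the textbook LDF metrics", {
  tri <- fixture_triangle_ldf()          # descent -0.1/s, ascent +0.1/s
  m <- ldf_metrics(tri, laser_onset = 30)
  expect_equal(m$rate_coefficient, 1, tolerance = 0.02)
  expect_equal(m$fwhm_transit, 5, tolerance = 0.3)
  # the 500-ms median filter rounds the apex slightly
  expect_equal(m$min_during_stim, 0.5, tolerance = 0.03)
  expect_equal(m$t_min, 5, tolerance = 0.1)
  expect_true(is.na(m$latency_50))       # never strictly below 50%
  expect_equal(m$late_mean, 1, tolerance = 1e-6)
})

test_that("asymmetric descent/ascent slopes set the rate coefficient", {
  fs <- 20
  tt <- seq(0, 190 - 1 / fs, by = 1 / fs)
  v <- rep(1, length(tt))
  down <- tt >= 30 & tt < 32.5; up <- tt >= 32.5 & tt < 37.5
  v[down] <- 1 - 0.2 * (tt[down] - 30)          # -0.2/s for 2.5 s -> 0.5
  v[up] <- 0.5 + 0.1 * (tt[up] - 32.5)          # +0.1/s for 5 s -> 1
  m <- ldf_metrics(time_series(v, fs), laser_onset = 30)
  expect_equal(m$rate_coefficient, 0.5, tolerance = 0.02)
  # time reversal swaps the limbs: reciprocal coefficient
  vr <- rep(1, length(tt))
  down2 <- tt >= 30 & tt < 35; up2 <- tt >= 35 & tt < 37.5
  vr[down2] <- 1 - 0.1 * (tt[down2] - 30)
  vr[up2] <- 0.5 + 0.2 * (tt[up2] - 35)
  mr <- ldf_metrics(time_series(vr, fs), laser_onset = 30)
  expect_equal(mr$rate_coefficient, 1 / m$rate_coefficient, tolerance = 0.05)
})

test_that("a flat trace yields unit flow and missing dip metrics", {
  flat <- time_series(rep(1, 190 * 20), 20)
  m <- ldf_metrics(flat, laser_onset = 30)
  expect_equal(m$min_during_stim, 1)
  expect_true(is.na(m$latency_50))
  expect_equal(m$late_mean, 1)
})

test_that("LDF metrics are invariant to raw amplitude scaling", {
  tri <- fixture_triangle_ldf()
  scaled <- tri; scaled$values <- 250 * tri$values
  a <- ldf_metrics(tri, 30); b <- ldf_metrics(scaled, 30)
  for (f in c("min_during_stim", "fwhm_transit", "rate_coefficient",
              "late_mean"))
    expect_equal(a[[f]], b[[f]], label = f)
})

test_that("syncope alignment re-references trials and averages exactly", {
  set.seed(41)
  v <- rnorm(3000)
  a <- time_series(v, 20)
  al1 <- align_to_syncope(list(a), onsets = 60, pre = 10, post = 20)
  seg <- cut_windows(a, 60, 10, 20)[[1]]
  expect_equal(al1$mean$values, seg$values)
  # identical trials at different onsets: zero variance across trials
  b <- time_series(c(rep(0, 400), v), 20)        # same signal, +20 s offset
  al2 <- align_to_syncope(list(a, b), onsets = c(60, 80), pre = 10, post = 20)
  expect_equal(al2$segments[[1]]$values, al2$segments[[2]]$values)
  expect_message(expect_null(align_to_syncope(list(a), numeric(0))),
                 "no syncope")
})

test_that("the programmed event order (HR min, LDF min, power drop) is recovered", {
  g <- generate_session(tiny_generator_config(seed = 18))
  ses <- g$session; tr <- g$truth
  hr <- heart_rate(ses$streams$ecg)
  seqs <- syncope_event_sequence(hr, ses$streams$ldf, tr$syncope, ses$lasers)
  expect_equal(nrow(seqs), nrow(tr$syncope))
  expect_true(all(seqs$hr_min < seqs$ldf_min))
  expect_true(all(seqs$ldf_min < seqs$power_drop))
})

test_that("stimulation-window statistics use the stated windows", {
  seg <- time_series(rep(1, 90 * 10), 10)
  seg$t0 <- -30
  expect_equal(stim_window_stats(seg, "hr"), list(stim = 1, post = 1))
  v <- rep(1, 900)
  tt <- seg$t0 + (seq_along(v) - 1) / 10
  v[tt >= 0 & tt < 30] <- 0.6
  seg2 <- seg; seg2$values <- v
  st <- stim_window_stats(seg2, "hr")
  expect_equal(st$stim, 0.6)
  # trace ending before the post window: post reported missing
  short <- time_series(rep(1, 40 * 10), 10); short$t0 <- -10
  expect_true(is.na(stim_window_stats(short, "hr")$post))
})
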