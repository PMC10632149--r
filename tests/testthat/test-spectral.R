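# Wavelet/FFT power analysis, syncope detection, and the cluster
# permutation test.

test_that("the notch filter removes 60 Hz and spares the passband", {
  x60 <- fixture_sinusoid(60, 4, 500)
  expect_lt(stats::sd(notch_filter(x60)$values), 0.1 * stats::sd(x60$values))
  x10 <- fixture_sinusoid(10, 4, 500)
  expect_equal(stats::sd(notch_filter(x10)$values), stats::sd(x10$values),
               tolerance = 0.05)
  # mixture: output should be the clean 10-Hz component
  mix <- x10
  mix$values <- x10$values + x60$values
  out <- notch_filter(mix)
  expect_gt(stats::cor(out$values, x10$values), 0.99)
  expect_error(notch_filter(time_series(rnorm(100), 100)), "too low")
})

test_that("wavelet frequencies are 80 log-spaced values from 0.5 to 120", {
  f <- wavelet_freqs()
  expect_length(f, 80)
  expect_equal(f[1], 0.5)
  expect_equal(f[80], 120)
  expect_equal(diff(log(f)), rep(diff(log(f))[1], 79), tolerance = 1e-12)
})

test_that("baseline normalization fixes every row mean at exactly 1", {
  set.seed(2)
  s <- time_series(rnorm(4000), 400, label = "eeg")
  sp <- wavelet_power(s, time_decimate = 2)
  expect_true(sp$normalized)
  expect_equal(rowMeans(sp$power), rep(1, 80), tolerance = 1e-9)
  # explicit baseline window: mean of 1 over those columns per row
  sp2 <- wavelet_power(s, analysis_window(0, 4, "baseline"), time_decimate = 2)
  cols <- sp2$times < 4
  expect_equal(rowMeans(sp2$power[, cols]), rep(1, 80), tolerance = 1e-9)
  expect_error(suppressWarnings(wavelet_power(time_series(rep(0, 2000), 400))),
               "zero baseline")
})

test_that("renormalizing with the same baseline is a no-op", {
  set.seed(3)
  s <- time_series(rnorm(3000), 300)
  sp <- wavelet_power(s, analysis_window(0, 5, "baseline"), time_decimate = 3)
  again <- normalize_spectrogram(sp)
  expect_equal(again$power, sp$power, tolerance = 1e-12)
})

test_that("a pure sinusoid localizes at the nearest frequency bin", {
  freqs <- wavelet_freqs()
  # sweep a representative set of centre frequencies across the full range
  for (fb in freqs[c(5, 18, 33, 47, 61, 74, 80)]) {
    s <- fixture_sinusoid(fb, max(6, 12 / fb), 500)
    sp <- wavelet_power(s, normalize = FALSE, time_decimate = 4)
    mid <- ncol(sp$power) %/% 2
    expect_equal(which.max(sp$power[, mid]),
                 which.min(abs(log(freqs) - log(fb))),
                 tolerance = 1,
                 label = sprintf("peak row at %.3g Hz", fb))
  }
})

test_that("a 0.3x amplitude step reads as 0.09 normalized band power", {
  stp <- fixture_step_lfp()
  sp <- wavelet_power(stp, analysis_window(0, 10, "baseline"),
                      time_decimate = 5)
  bm <- colMeans(sp$power[sp$freqs >= 8 & sp$freqs <= 100, ])
  inside <- mean(bm[sp$times >= 12 & sp$times <= 18])
  expect_equal(inside, 0.09, tolerance = 0.1)
})

test_that("syncope detection finds the 50% onset and 80% offset", {
  stp <- fixture_step_lfp()   # amplitude x0.3 -> power 0.09 in [10, 20] s
  sp <- wavelet_power(stp, analysis_window(0, 10, "baseline"),
                      time_decimate = 5)
  ev <- detect_syncope(sp, laser_onset = 0)
  expect_equal(ev$onset, 10, tolerance = 1)
  expect_equal(ev$offset, 20, tolerance = 1)
  expect_gt(ev$offset, ev$onset)
  # constant power map: nothing to detect
  flat <- sp
  flat$power[] <- 1
  expect_null(detect_syncope(flat, laser_onset = 0))
  expect_error(detect_syncope(sp, band = c(500, 600)), "band")
})

test_that("lowering the onset fraction can only delay the onset", {
  stp <- fixture_step_lfp()
  sp <- wavelet_power(stp, analysis_window(0, 10, "baseline"),
                      time_decimate = 5)
  onsets <- vapply(c(0.8, 0.5, 0.3, 0.15), function(fr) {
    ev <- detect_syncope(sp, laser_onset = 0, onset_frac = fr)
    if (is.null(ev)) Inf else ev$onset
  }, numeric(1))
  expect_true(all(diff(onsets) >= 0))
})

test_that("light-contrast maps subtract mean off from mean on", {
  set.seed(4)
  on <- replicate(3, matrix(rnorm(50), 5), simplify = FALSE)
  expect_equal(light_contrast_map(on, on), matrix(0, 5, 10))
  off <- lapply(on, function(m) m - 2)
  expect_equal(light_contrast_map(on, off), matrix(2, 5, 10))
  expect_equal(light_contrast_map(on[1], off[1]), matrix(2, 5, 10))
  expect_error(light_contrast_map(on, list(matrix(0, 2, 2))), "grids")
})

test_that("union-find component sizes agree with a brute-force BFS oracle", {
  set.seed(11)
  for (i in 1:25) {
    mask <- matrix(runif(20 * 15) < 0.35, 20, 15)
    expect_equal(sort(synckit:::component_sizes(mask)),
                 sort(bfs_component_sizes(mask)))
  }
  # diagonal touching must NOT connect (4-connectivity)
  m <- matrix(FALSE, 3, 3); m[1, 1] <- m[2, 2] <- TRUE
  expect_equal(sort(synckit:::component_sizes(m)), c(1L, 1L))
})

test_that("an injected broadband power drop yields a negative cluster", {
  set.seed(7)
  d <- c(20, 30)
  off <- replicate(6, matrix(1 + 0.15 * rnorm(prod(d)), d[1]), simplify = FALSE)
  on <- replicate(6, {
    m <- matrix(1 + 0.15 * rnorm(prod(d)), d[1])
    m[5:16, 10:25] <- m[5:16, 10:25] - 0.5   # 50% drop block
    m
  }, simplify = FALSE)
  res <- cluster_permutation_test(on, off, n_perm = 300, seed = 1)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  expect_true(all(sig$sign == -1))
  big <- sig[which.max(sig$area), ]
  expect_lte(big$freq_lo, 6)
  expect_gte(big$freq_hi, 15)
  expect_lte(big$time_lo, 11)
  expect_gte(big$time_hi, 24)
})

test_that("identical trials give a degenerate null and no clusters", {
  m <- matrix(1, 8, 12)
  on <- replicate(4, m, simplify = FALSE)
  expect_warning(res <- cluster_permutation_test(on, on, n_perm = 200,
                                                 seed = 2), "identical")
  expect_equal(nrow(res$clusters), 0)
})

test_that("FFT band power respects the six fixed band definitions", {
  b <- eeg_bands()
  expect_equal(b$lo, c(1, 4, 8, 13, 30, 61))
  expect_equal(b$hi, c(4, 8, 13, 30, 59, 120))
  # 10-Hz sinusoid: alpha holds nearly all 1-120 Hz power
  s <- fixture_sinusoid(10, 8, 500)
  bp <- band_power_fft(s)
  tot <- rowSums(bp[, b$band])
  expect_true(all(bp$alpha / tot >= 0.95))
  # equal-amplitude 2 + 50 Hz mixture: delta and low gamma split the power
  tt <- ts_times(s)
  mix <- time_series(sin(2 * pi * 2 * tt) + sin(2 * pi * 50 * tt), 500)
  bp2 <- band_power_fft(mix)
  tot2 <- rowSums(bp2[, b$band])
  expect_equal(mean(bp2$delta / tot2), 0.5, tolerance = 0.02)
  expect_equal(mean(bp2$low_gamma / tot2), 0.5, tolerance = 0.02)
  expect_error(band_power_fft(fixture_sinusoid(10, 1, 500)), "shorter")
})

test_that("white-noise band power scales with band width", {
  set.seed(5)
  s <- time_series(rnorm(240 * 500), 500)
  bp <- band_power_fft(s)
  b <- eeg_bands()
  per_hz <- colMeans(bp[, b$band]) / (b$hi - b$lo)
  expect_lt(max(per_hz) / min(per_hz), 1.12)
  # trailing partial segments are dropped
  s2 <- time_series(rnorm(2501), 500)
  expect_equal(nrow(band_power_fft(s2)), 2)
})
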