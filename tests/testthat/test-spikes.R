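# Unit curation, Poisson inactivity statistics, response latency, and
# activation classification.

test_that("stationary units pass the drift screen, part-silent units fail", {
  set.seed(14)
  units <- lapply(1:60, function(i)
    spike_train(paste0("u", i), "SSp", poisson_train(5, 600)))
  flags <- flag_drifting_units(units, 600)
  expect_lt(mean(flags), 0.05)
  half <- spike_train("h", "SSp", poisson_train(10, 300))
  expect_true(flag_drifting_units(list(half), 600))
  # empty trains defer to the low-rate filter
  expect_true(is.na(flag_drifting_units(
    list(spike_train("e", "SSp", numeric(0))), 600)))
  expect_error(flag_drifting_units(units, 50), "60 s")
})

test_that("the 0.25-Hz rule is strict: exactly 0.25 Hz is retained", {
  u150 <- spike_train("a", "SSp", seq(2, 598, length.out = 150))
  u149 <- spike_train("b", "SSp", seq(2, 598, length.out = 149))
  empty <- spike_train("c", "SSp", numeric(0))
  flags <- flag_low_rate_units(list(u150, u149, empty), 600)
  expect_identical(flags, c(FALSE, TRUE, TRUE))
})

test_that("binning is half-open with edge spikes in the later bin", {
  u <- spike_train("u", "SSp", c(0.05, 0.15))
  br <- bin_rates(list(u), dt = 0.1, t_end = 0.5)
  expect_equal(br$counts[1, ], c(1, 1, 0, 0, 0))
  edge <- spike_train("e", "SSp", 0.1)
  expect_equal(bin_rates(list(edge), dt = 0.1, t_end = 0.3)$counts[1, ],
               c(0, 1, 0))
  set.seed(3)
  pois <- spike_train("p", "SSp", poisson_train(20, 500))
  expect_equal(mean(bin_rates(list(pois), t_end = 500)$counts), 2,
               tolerance = 0.05)
  # counts conserve total in-range spikes
  expect_equal(sum(bin_rates(list(pois), t_end = 500)$counts),
               sum(pois$spike_times < 500))
})

test_that("required silence length follows the Poisson formula with a cap", {
  expect_equal(inactivity_bins_required(2), 2303)      # ceil(4.6052/0.002)
  expect_equal(inactivity_bins_required(0.5), 4000)    # 9210 capped
  expect_equal(inactivity_bins_required(2, P0 = 1), 0)
  lam <- seq(0.2, 40, by = 0.37)
  k <- inactivity_bins_required(lam)
  expect_true(all(diff(k) <= 0))
  expect_true(all(k <= 4000))
  expect_error(inactivity_bins_required(0), "lambda")
})

test_that("response probability matches the Poisson survival oracle", {
  expect_equal(response_probability(0, 5, 4, 0.1), 1)
  expect_equal(response_probability(8, 5, 4, 0.1), 1.09e-3, tolerance = 1e-2)
  expect_equal(response_probability(1, 5, 4, 25), 1, tolerance = 1e-12)
  for (lam in c(0.3, 2, 8)) for (N in c(1, 4)) for (t in c(0.01, 0.2, 1)) {
    mu <- N * lam * t
    for (n in unique(round(c(1, mu, mu + 3 * sqrt(mu) + 2, 4 * mu + 10)))) {
      if (n < 1) next
      expect_equal(response_probability(n, lam, N, t),
                   stats::ppois(n - 1, mu, lower.tail = FALSE),
                   tolerance = 1e-10,
                   label = sprintf("n=%d lam=%g N=%d t=%g", n, lam, N, t))
    }
  }
})

test_that("response probability is monotone in n, t, lambda and N", {
  p_n <- vapply(1:30, function(n) response_probability(n, 5, 4, 0.1), 0)
  expect_true(all(diff(p_n) <= 0))
  p_t <- vapply(seq(0.01, 1, 0.01), function(t)
    response_probability(5, 5, 4, t), 0)
  expect_true(all(diff(p_t) >= 0))
  p_l <- vapply(seq(0.5, 20, 0.5), function(l)
    response_probability(5, l, 4, 0.1), 0)
  expect_true(all(diff(p_l) >= 0))
})

test_that("silence time-locked to syncope onset flags a unit, tonic firing does not", {
  syn <- data.frame(onset = 50, offset = 60)
  # silenced exactly at onset
  set.seed(8)
  sil <- spike_train("s", "SSp", c(poisson_train(5, 50), 70 + poisson_train(5, 30)),
                     baseline_rate = 5)
  r <- inactive_at_syncope(sil, syn, extent = c(0, 100))
  expect_true(r$inactive)
  expect_gt(r$time_off, 0.95)
  # regular fast firing throughout
  reg <- spike_train("r", "SSp", seq(0.05, 100, by = 0.1), baseline_rate = 10)
  r2 <- inactive_at_syncope(reg, syn, extent = c(0, 100))
  expect_false(r2$inactive)
  expect_true(is.na(r2$time_off))
  # window truncation warns
  late <- data.frame(onset = 95, offset = 120)
  expect_warning(inactive_at_syncope(sil, late, extent = c(0, 100)),
                 "truncat")
})

test_that("suppressed units are caught and stationary units rarely flagged", {
  set.seed(19)
  syn <- data.frame(onset = 50, offset = 60)
  lam <- runif(40, 2, 8)
  sens <- vapply(lam, function(l) {
    u <- spike_train("s", "SSp",
                     c(poisson_train(l, 50), 62 + poisson_train(l, 38)),
                     baseline_rate = l)
    inactive_at_syncope(u, syn, extent = c(0, 100))$inactive
  }, logical(1))
  fp <- vapply(lam, function(l) {
    u <- spike_train("n", "SSp", poisson_train(l, 100), baseline_rate = l)
    inactive_at_syncope(u, syn, extent = c(0, 100))$inactive
  }, logical(1))
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fp), 0.1)
})

test_that("random-window control reports per-region paired percentages", {
  set.seed(22)
  syn <- data.frame(onset = 50, offset = 60)
  units <- c(
    lapply(1:6, function(i) {
      l <- runif(1, 3, 6)
      spike_train(paste0("sup", i), "SSp",
                  c(poisson_train(l, 50), 61 + poisson_train(l, 39)),
                  baseline_rate = l)
    }),
    lapply(1:6, function(i) {
      l <- runif(1, 3, 6)
      spike_train(paste0("null", i), "PVZ", poisson_train(l, 100),
                  baseline_rate = l)
    }))
  out <- random_window_control(units, syn, duration = 100,
                               lasers = laser_events(45, 10, 20),
                               n_draws = 2, margin = 2, seed = 4)
  expect_setequal(out$table$region, c("SSp", "PVZ"))
  ssp <- out$table[out$table$region == "SSp", ]
  expect_gt(ssp$pct_inactive_syncope, ssp$pct_inactive_control)
  expect_equal(ssp$n_units, 6)
  # single unit, single region: one-row table, no t-test
  one <- random_window_control(units[1], syn, duration = 100,
                               lasers = laser_events(45, 10, 20),
                               margin = 2, seed = 5)
  expect_equal(nrow(one$table), 1)
  expect_null(one$t_test)
})

test_that("latency estimation recovers programmed burst latencies", {
  onsets <- c(100, 200, 300, 400)
  errs <- sapply(1:20, function(s) {
    set.seed(400 + s)
    st <- simulate_step_train(5, 50, latency = 0.05, onsets = onsets,
                              extent = c(0, 500))
    u <- spike_train("u", "SSp", unique(st), baseline_rate = 5)
    abs(laser_latency(u, onsets) - 0.05)
  })
  expect_lte(stats::median(errs), 0.01)
  # a silent unit never gets a latency
  mute <- spike_train("m", "SSp", numeric(0), baseline_rate = 1)
  expect_true(is.na(laser_latency(mute, onsets)))
})

test_that("null units almost never produce a sub-250-ms latency", {
  onsets <- c(100, 200, 300, 400)
  hits <- sapply(1:60, function(s) {
    set.seed(900 + s)
    u <- spike_train("n", "SSp", poisson_train(6, 500), baseline_rate = 6)
    lat <- laser_latency(u, onsets)
    !is.na(lat) && lat < 0.25
  })
  expect_lte(mean(hits), 0.01 + 1e-9)
})

test_that("stronger responses never lengthen the estimated latency", {
  onsets <- c(100, 200, 300, 400)
  lat_lo <- lat_hi <- numeric(12)
  for (s in 1:12) {
    set.seed(70 + s)
    st1 <- simulate_step_train(5, 30, 0.08, onsets, extent = c(0, 500),
                               burst_rate = 200)
    set.seed(70 + s)
    st2 <- simulate_step_train(5, 60, 0.08, onsets, extent = c(0, 500),
                               burst_rate = 400)
    lat_lo[s] <- laser_latency(spike_train("a", "SSp", unique(st1),
                                           baseline_rate = 5), onsets)
    lat_hi[s] <- laser_latency(spike_train("b", "SSp", unique(st2),
                                           baseline_rate = 5), onsets)
  }
  expect_lte(mean(lat_hi, na.rm = TRUE), mean(lat_lo, na.rm = TRUE) + 1e-9)
})

test_that("activation needs all three criteria", {
  bt <- seq(0.05, 500, by = 0.1)
  onsets <- c(100, 200, 300, 400)
  zero <- rep(0, length(bt))
  r0 <- classify_laser_activated(zero, bt, onsets, latency = 0.05)
  expect_false(r0$criterion1)   # "positive" read strictly
  expect_false(r0$activated)
  pos <- zero
  for (on in onsets) pos[bt >= on & bt < on + 0.8] <- 1
  r1 <- classify_laser_activated(pos, bt, onsets, latency = 0.05)
  expect_true(r1$criterion1 && r1$criterion2 && r1$criterion3)
  expect_true(r1$activated)
  # slow responder fails only criterion 3
  r2 <- classify_laser_activated(pos, bt, onsets, latency = 0.4)
  expect_true(r2$criterion1 && r2$criterion2)
  expect_false(r2$criterion3 || r2$activated)
  # one onset window not exceeding its pre window fails criterion 2
  mixed <- pos
  mixed[bt >= onsets[2] - 0.8 & bt < onsets[2]] <- 2
  r3 <- classify_laser_activated(mixed, bt, onsets, latency = 0.05)
  expect_false(r3$criterion2)
  expect_error(classify_laser_activated(pos, bt, numeric(0), 0.05), "onset")
})

test_that("region summaries aggregate medians and percentages", {
  cl <- data.frame(
    unit_id = paste0("u", 1:5),
    region = c("SSp", "SSp", "SSp", "PVZ", "PVZ"),
    latency = c(0.01, 0.02, 0.03, 0.2, NA),
    laser_activated = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    inactive_at_syncope = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    time_off = c(0.9, 0.8, 1, NA, NA))
  rs <- region_summary(cl)
  ssp <- rs[rs$region == "SSp", ]
  expect_equal(ssp$median_latency, 0.02)
  expect_equal(ssp$pct_inactive, 100)
  expect_equal(ssp$mean_time_off, 0.9)
  pvz <- rs[rs$region == "PVZ", ]
  expect_equal(pvz$pct_inactive, 0)
  expect_equal(pvz$n_activated, 0)
})
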