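# Split construction, encoder training, nearest-neighbour prediction,
# residual identities, and metrics.

test_that("a 600-s session with 4 lasers splits 5 test / 4 train / 1 val", {
  lasers <- laser_events(c(66, 129, 192, 255), 30, c(5, 10, 20, 20))
  sp <- make_split(600, lasers, seed = 1)
  expect_equal(sum(sp$role == "test_laser"), 4)
  expect_equal(sum(sp$role == "test_control"), 1)
  expect_equal(sum(sp$role == "train"), 4)
  expect_equal(sum(sp$role == "validation"), 1)
  expect_equal(sum(sp$end - sp$start), 5 * 63 + 5 * 50)
  # every laser window sits inside a test segment, never train/validation
  for (i in which(sp$role %in% c("train", "validation")))
    for (j in seq_len(nrow(lasers)))
      expect_true(lasers$onset[j] + lasers$duration[j] <= sp$start[i] ||
                    lasers$onset[j] >= sp$end[i])
  # control window holds no laser
  ctl <- sp[sp$role == "test_control", ]
  expect_true(all(lasers$onset >= ctl$end | lasers$onset + lasers$duration <=
                    ctl$start))
})

test_that("test segments are seed-invariant; assignment is seed-dependent", {
  lasers <- laser_events(c(66, 129, 192, 255), 30)
  a <- make_split(600, lasers, seed = 1)
  b <- make_split(600, lasers, seed = 2)
  expect_identical(a[a$role %in% c("test_laser", "test_control"), 1:2],
                   b[b$role %in% c("test_laser", "test_control"), 1:2])
  expect_identical(make_split(600, lasers, seed = 1), a)
  # with no lasers there is still a control test segment
  c0 <- make_split(300, NULL)
  expect_equal(sum(c0$role == "test_control"), 1)
  expect_equal(sum(c0$role == "test_laser"), 0)
  expect_error(make_split(100, laser_events(50, 30)), "exceed")
  expect_error(make_split(80, NULL), "too short|non-test")
})

test_that("zero rates train to a near-zero predictor", {
  set.seed(1)
  X <- matrix(rnorm(20 * 3000), 20)
  units <- list(spike_train("z", "SSp", numeric(0)))
  rates <- bin_rates(units, t_end = 100)
  sp <- make_split(100, NULL, seg_test = 20, seg_nontest = 20, seed = 1)
  # strong decay drives all weights (hence the prediction) to zero
  m <- train_encoder(X, rates, sp,
                     tiny_encoder_spec(lr = 5e-2, max_epochs = 400,
                                       patience = 400, weight_decay = 1e-2),
                     seed = 1)
  expect_lt(m$val_loss, 1e-4)
})

test_that("a noiseless linear read-out is recovered with high VE", {
  set.seed(2)
  nT <- 9000; d <- 10                        # 300 s at 30 Hz
  X <- matrix(0, d, nT)
  for (i in 1:d) X[i, ] <- as.numeric(stats::filter(rnorm(nT), rep(0.2, 5),
                                                    circular = TRUE))
  Wtrue <- matrix(rnorm(d * 4), 4, d)
  frames_of_bin <- round((seq(0.05, 300, by = 0.1)) * 30 + 0.5)
  Ytrue <- pmax(Wtrue %*% X[, frames_of_bin] + 3, 0)
  rates <- structure(
    list(counts = Ytrue * 0.1, dt = 0.1, t0 = 0,
         unit_ids = paste0("u", 1:4), regions = rep("SSp", 4),
         bin_times = seq(0.05, 300, by = 0.1)),
    class = "binned_rates")
  sp <- make_split(300, NULL, seed = 3)
  m <- train_encoder(X, rates, sp, encoder_spec(hidden = 24,
                                                conv_channels = 12,
                                                kernel = 5, latent = 8,
                                                lr = 5e-3, max_epochs = 150,
                                                patience = 15), seed = 2)
  roles <- synckit:::split_bin_roles(sp, rates$bin_times)
  tst <- which(roles == "test_control")
  pr <- predict(m, X, rates$bin_times[tst])
  mm <- model_metrics(Ytrue[, tst], pr$pred, rates$bin_times[tst], sp)
  expect_gte(stats::median(mm$ve_control), 0.9)
})

test_that("intact behaviour beats time-shuffled behaviour", {
  g <- generate_session(tiny_generator_config(seed = 31, duration = 300,
                                              laser_onsets = 66,
                                              laser_hz = 20,
                                              streams = character(0)))
  ses <- g$session
  rates <- bin_rates(ses$units, t_end = 300)
  sp <- make_split(300, ses$lasers, seed = 1)
  m1 <- train_encoder(ses$behavior, rates, sp, tiny_encoder_spec(), seed = 1)
  set.seed(99)
  shuf <- ses$behavior
  idx <- sample(ncol(shuf$x_movie))
  shuf$x_movie <- shuf$x_movie[, idx]
  shuf$x_motion <- shuf$x_motion[, idx]
  m2 <- train_encoder(shuf, rates, sp, tiny_encoder_spec(), seed = 1)
  expect_lt(m1$val_loss, m2$val_loss)
})

test_that("training never touches test-segment neural data", {
  g <- generate_session(tiny_generator_config(seed = 32, duration = 300,
                                              laser_onsets = 66,
                                              streams = character(0)))
  ses <- g$session
  rates <- bin_rates(ses$units, t_end = 300)
  sp <- make_split(300, ses$lasers, seed = 1)
  roles <- synckit:::split_bin_roles(sp, rates$bin_times)
  m1 <- train_encoder(ses$behavior, rates, sp, tiny_encoder_spec(), seed = 7)
  zeroed <- rates
  zeroed$counts[, roles %in% c("test_laser", "test_control")] <- 0L
  m2 <- train_encoder(ses$behavior, zeroed, sp, tiny_encoder_spec(), seed = 7)
  expect_identical(m1$par, m2$par)
})

test_that("nearest-neighbour prediction handles degenerate neighbourhoods", {
  L <- 4
  lat0 <- rnorm(L)
  train_lat <- cbind(matrix(lat0, L, 60), matrix(rnorm(L * 40) + 5, L))
  train_rates <- cbind(matrix(2, 3, 60), matrix(9, 3, 40))
  # test latent duplicated >= k times with identical rates: exact recovery
  pred <- nn_latent_predict(train_lat, train_rates, matrix(lat0, L, 1), k = 50)
  expect_equal(pred[, 1], rep(2, 3))
  # k = all training points: the training mean everywhere
  pred_all <- nn_latent_predict(train_lat, train_rates,
                                matrix(rnorm(L * 5), L), k = 100)
  expect_equal(pred_all, matrix(rowMeans(train_rates), 3, 5))
  expect_warning(nn_latent_predict(train_lat, train_rates,
                                   matrix(lat0, L, 1), k = 500), "clipped")
})

test_that("recorded equals nn prediction plus residual, bin-wise", {
  set.seed(5)
  rec <- matrix(rpois(200, 4), 4)
  nn <- matrix(runif(200), 4)
  bt <- seq(0.05, by = 0.1, length.out = 50)
  res <- compute_residuals(rec, nn, bt, lasers = 2, syncope = NULL,
                           onset_window = 0.4, pre_window = 0.4)
  expect_equal(res$residual + nn, rec, tolerance = 1e-14)
})

test_that("residual window summaries isolate injected laser excess", {
  nT <- 700
  bt <- seq(0.05, by = 0.1, length.out = nT)
  onsets <- c(20, 40)
  rec <- matrix(5, 2, nT)
  nn <- matrix(5, 2, nT)
  for (on in onsets) rec[, bt >= on & bt < on + 0.8] <- 7   # +2 Hz injected
  res <- compute_residuals(rec, nn, bt, onsets,
                           syncope = data.frame(onset = 55, offset = 60))
  expect_equal(res$summaries$laser_onset, c(2, 2))
  expect_equal(res$summaries$pre_laser, c(0, 0))
  expect_equal(res$summaries$syncope, c(0, 0))
  # identical prediction: all summaries zero
  res0 <- compute_residuals(rec, rec, bt, onsets)
  expect_true(all(res0$summaries$laser_onset == 0))
  # windows outside the covered bins error
  expect_error(compute_residuals(rec, nn, bt, c(20, 200)), "test segments")
})

test_that("metrics report perfect, mean and degenerate predictors correctly", {
  set.seed(6)
  bt <- seq(0.05, by = 0.1, length.out = 630)
  sp <- structure(data.frame(start = 0, end = 63, role = "test_control",
                             laser_onset = NA_real_),
                  class = c("split_plan", "data.frame"))
  rec <- matrix(rnorm(2 * 630, 10), 2)
  mm <- model_metrics(rec, rec, bt, sp)
  expect_equal(mm$ve_control, c(1, 1))
  expect_equal(mm$r_control, c(1, 1))
  mean_pred <- matrix(rowMeans(rec), 2, 630)
  mm2 <- model_metrics(rec, mean_pred, bt, sp)
  expect_equal(mm2$ve_control, c(0, 0), tolerance = 0.05)
  expect_true(all(is.na(mm2$r_control)))
  flat <- matrix(3, 2, 630)
  mm3 <- model_metrics(flat, rec, bt, sp)
  expect_true(all(is.na(mm3$ve_control)))
})

test_that("VE is invariant to unit relabelling and consistent rescaling", {
  set.seed(8)
  bt <- seq(0.05, by = 0.1, length.out = 630)
  sp <- structure(data.frame(start = 0, end = 63, role = "test_control",
                             laser_onset = NA_real_),
                  class = c("split_plan", "data.frame"))
  rec <- matrix(rnorm(3 * 630, 5), 3)
  pred <- rec + 0.3 * matrix(rnorm(3 * 630), 3)
  base <- model_metrics(rec, pred, bt, sp)$ve_control
  perm <- c(3, 1, 2)
  expect_equal(model_metrics(rec[perm, ], pred[perm, ], bt, sp)$ve_control,
               base[perm])
  expect_equal(model_metrics(2 * rec + 1, 2 * pred + 1, bt, sp)$ve_control,
               base, tolerance = 1e-12)
})
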