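# Behaviour -> neural encoding: segmented train/validation/test split, a
# small multi-layer network (linear -> temporal convolution -> ReLU ->
# latent linear -> output linear) fit with AdamW and early stopping,
# nearest-neighbour latent prediction, residuals, and metrics.

#' Segmented train/validation/test split
#'
#' Test segments are one 63-s laser-free control window plus one 63-s window
#' per laser (-3 s to +60 s around onset), so no laser period can leak into
#' training. The remaining recording is tiled into 50-s segments, of which
#' 80% are assigned to training and 20% to validation (the segment length
#' guards against leakage through the slow autocorrelation of behaviour).
#'
#' @param duration session length in seconds.
#' @param lasers laser event table (or numeric onsets; may be empty).
#' @param seg_nontest non-test segment length in seconds (50).
#' @param seg_test test segment length in seconds (63).
#' @param test_pre seconds of the test window before laser onset (3).
#' @param val_frac fraction of non-test segments used for validation (0.2).
#' @param seed seed for the train/validation assignment (test segments are
#'   deterministic and unaffected).
#' @return `data.frame` of class `split_plan`: `start`, `end`, `role`
#'   (`train`, `validation`, `test_laser`, `test_control`), `laser_onset`.
#' @export
make_split <- function(duration, lasers = NULL, seg_nontest = 50,
                       seg_test = 63, test_pre = 3, val_frac = 0.2,
                       seed = 1) {
  onsets <- if (is.data.frame(lasers)) lasers$onset else
    as.numeric(lasers %||% numeric(0))
  onsets <- sort(onsets)
  test <- NULL
  if (length(onsets)) {
    test <- data.frame(start = onsets - test_pre,
                       end = onsets - test_pre + seg_test,
                       role = "test_laser", laser_onset = onsets)
    if (any(test$start < 0) || any(test$end > duration))
      stop_validation("laser test windows exceed the recording by ",
                      signif(max(c(0 - test$start, test$end - duration)), 3), " s")
    if (nrow(test) > 1 && any(test$start[-1] < test$end[-nrow(test)]))
      stop_validation("laser test windows overlap; sessions with closer ",
                      "lasers are not supported")
  }
  # gaps not covered by laser test windows, in temporal order
  gap_start <- c(0, if (!is.null(test)) test$end)
  gap_end <- c(if (!is.null(test)) test$start, duration)
  gaps <- data.frame(start = gap_start, end = gap_end)
  gaps <- gaps[gaps$end - gaps$start > 1e-9, , drop = FALSE]
  # control: first gap that can host a full test segment
  ctrl_gap <- which(gaps$end - gaps$start >= seg_test)
  if (!length(ctrl_gap))
    stop_validation("no ", seg_test, "-s laser-free span for the control ",
                    "test segment; session too short by at least ",
                    signif(seg_test - max(gaps$end - gaps$start), 3), " s")
  ci <- ctrl_gap[1]
  control <- data.frame(start = gaps$start[ci], end = gaps$start[ci] + seg_test,
                        role = "test_control", laser_onset = NA_real_)
  gaps$start[ci] <- control$end
  gaps <- gaps[gaps$end - gaps$start > 1e-9, , drop = FALSE]
  nontest <- do.call(rbind, lapply(seq_len(nrow(gaps)), function(i) {
    n <- floor((gaps$end[i] - gaps$start[i]) / seg_nontest + 1e-9)
    if (n < 1) return(NULL)
    data.frame(start = gaps$start[i] + (seq_len(n) - 1) * seg_nontest,
               end = gaps$start[i] + seq_len(n) * seg_nontest,
               role = "train", laser_onset = NA_real_)
  }))
  if (is.null(nontest) || nrow(nontest) < 2L)
    stop_validation("fewer than 2 non-test segments fit; need at least ",
                    2 * seg_nontest, " s outside the test windows")
  n_val <- max(1L, as.integer(round(val_frac * nrow(nontest))))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nontest$role[sample.int(nrow(nontest), n_val)] <- "validation"
  plan <- rbind(test, control, nontest)
  plan <- plan[order(plan$start), ]
  rownames(plan) <- NULL
  class(plan) <- c("split_plan", "data.frame")
  plan
}

# Role of each bin centre under a split plan (NA outside all segments).
split_bin_roles <- function(split, bin_times) {
  roles <- rep(NA_character_, length(bin_times))
  for (i in seq_len(nrow(split))) {
    sel <- bin_times >= split$start[i] & bin_times < split$end[i]
    roles[sel] <- split$role[i]
  }
  roles
}

#' Architecture and optimizer settings of the encoding network
#'
#' The layer sequence follows the behaviour-encoding design: a linear layer,
#' a one-dimensional temporal convolution whose output is subsampled at the
#' neural bin centres, a ReLU, a narrower linear layer whose output is the
#' latent time series, and a linear output layer; fit with AdamW and early
#' stopping on the validation segments.
#'
#' @param hidden width of the first linear layer.
#' @param conv_channels channels of the temporal convolution.
#' @param kernel convolution kernel length in frames (odd; 9 frames = 0.3 s
#'   at 30 Hz).
#' @param latent latent dimensionality (must be `< hidden`).
#' @param lr learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param max_epochs,patience early-stopping budget on validation loss.
#' @export
encoder_spec <- function(hidden = 64, conv_channels = 32, kernel = 9,
                         latent = 16, lr = 2e-3, weight_decay = 1e-4,
                         max_epochs = 100, patience = 8) {
  if (latent >= hidden)
    stop_validation("latent dimension must be smaller than the hidden width")
  if (kernel %% 2 == 0) stop_validation("kernel must be odd")
  as.list(environment())
}

relu <- function(x) pmax(x, 0)

# Build the unrolled conv-input matrix for the given bin-centre frames:
# rows = bins, cols = K * hidden (frame offset-major blocks).
unroll_windows <- function(Z1, centres, kernel) {
  half <- (kernel - 1) / 2
  nb <- length(centres)
  h1 <- ncol(Z1)
  U <- matrix(0, nb, kernel * h1)
  for (j in seq_len(kernel)) {
    rows <- pmin(pmax(centres + j - 1L - half, 1L), nrow(Z1))
    U[, ((j - 1) * h1 + 1):(j * h1)] <- Z1[rows, , drop = FALSE]
  }
  U
}

encoder_forward <- function(par, Xf, centres, kernel, rows = NULL) {
  if (is.null(rows)) {
    Z1 <- sweep(Xf %*% par$W1, 2, par$b1, `+`)
  } else {
    # only `rows` of the first-layer output are touched by these windows
    Z1 <- matrix(0, nrow(Xf), length(par$b1))
    Z1[rows, ] <- sweep(Xf[rows, , drop = FALSE] %*% par$W1, 2, par$b1, `+`)
  }
  U <- unroll_windows(Z1, centres, kernel)
  A <- sweep(U %*% par$Wc, 2, par$bc, `+`)
  H <- relu(A)
  Lat <- sweep(H %*% par$Wl, 2, par$bl, `+`)
  Y <- sweep(Lat %*% par$Wo, 2, par$bo, `+`)
  list(Z1 = Z1, U = U, A = A, H = H, Lat = Lat, Y = Y)
}

#' Fit the behaviour-to-neural encoding network
#'
#' @param behavior behaviour input: a [behavior_streams] (its `x_movie` and
#'   `x_motion` are stacked) or a plain `components x frames` matrix.
#' @param rates a [bin_rates()] result (targets in Hz = counts / dt).
#' @param split a [make_split()] plan.
#' @param spec an [encoder_spec()].
#' @param seed seed for weight initialization.
#' @param fps behaviour frame rate (taken from `behavior` if available).
#' @param verbose print per-epoch losses.
#' @return object of class `behavior_encoder` with the fitted weights, input
#'   normalization, split, and the train/validation loss history.
#' @export
train_encoder <- function(behavior, rates, split, spec = encoder_spec(),
                          seed = 1, fps = NULL, verbose = FALSE) {
  if (inherits(behavior, "behavior_streams")) {
    fps <- fps %||% behavior$sample_rate
    X <- rbind(behavior$x_movie, behavior$x_motion)
  } else {
    X <- behavior
    fps <- fps %||% 30
  }
  stopifnot(inherits(rates, "binned_rates"))
  Xf <- t(X)                               # frames x components
  dt <- rates$dt
  bin_times <- rates$bin_times
  roles <- split_bin_roles(split, bin_times)
  centres_all <- pmin(pmax(round((bin_times - rates$t0) * fps + 0.5), 1L),
                      nrow(Xf))
  tr <- which(roles == "train")
  va <- which(roles == "validation")
  if (!length(tr) || !length(va))
    stop_validation("split plan yields empty train or validation bins")
  Y <- t(rates$counts) / dt                # bins x units (Hz)

  mu <- colMeans(Xf[centres_all[tr], , drop = FALSE])
  sd_ <- pmax(apply(Xf[centres_all[tr], , drop = FALSE], 2, stats::sd), 1e-6)
  Xf <- sweep(sweep(Xf, 2, mu, `-`), 2, sd_, `/`)

  d <- ncol(Xf); h1 <- spec$hidden; K <- spec$kernel
  C <- spec$conv_channels; L <- spec$latent; nu <- ncol(Y)
  set.seed(seed)
  init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  par <- list(W1 = init(d, h1), b1 = rep(0, h1),
              Wc = init(K * h1, C), bc = rep(0, C),
              Wl = init(C, L), bl = rep(0, L),
              Wo = init(L, nu), bo = colMeans(Y[tr, , drop = FALSE]))
  mstate <- lapply(par, function(p) p * 0)
  vstate <- lapply(par, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  half <- (K - 1) / 2
  # only frames inside a train/val conv window are touched during fitting
  needed <- sort(unique(pmin(pmax(
    as.vector(outer(centres_all[c(tr, va)], (-half):half, `+`)), 1L),
    nrow(Xf))))
  ctr <- centres_all[tr]; cva <- centres_all[va]
  Ytr <- Y[tr, , drop = FALSE]; Yva <- Y[va, , drop = FALSE]
  best <- list(loss = Inf, par = par, epoch = 0L)
  history <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  wait <- 0L
  for (epoch in seq_len(spec$max_epochs)) {
    fw <- encoder_forward(par, Xf, ctr, K, rows = needed)
    E <- fw$Y - Ytr
    train_loss <- mean(E^2)
    G <- 2 * E / length(E)
    grads <- list()
    grads$Wo <- crossprod(fw$Lat, G); grads$bo <- colSums(G)
    dLat <- G %*% t(par$Wo)
    grads$Wl <- crossprod(fw$H, dLat); grads$bl <- colSums(dLat)
    dH <- dLat %*% t(par$Wl)
    dA <- dH * (fw$A > 0)
    grads$Wc <- crossprod(fw$U, dA); grads$bc <- colSums(dA)
    dU <- dA %*% t(par$Wc)
    dZ1 <- matrix(0, nrow(Xf), h1)
    for (j in seq_len(K)) {
      rows <- pmin(pmax(ctr + j - 1L - half, 1L), nrow(Xf))
      blk <- dU[, ((j - 1) * h1 + 1):(j * h1), drop = FALSE]
      # rows within one offset are unique (distinct bin centres, stride >= 1)
      add <- rowsum(blk, rows)
      dZ1[as.integer(rownames(add)), ] <- dZ1[as.integer(rownames(add)), ] + add
    }
    grads$W1 <- crossprod(Xf[needed, , drop = FALSE],
                          dZ1[needed, , drop = FALSE])
    grads$b1 <- colSums(dZ1[needed, , drop = FALSE])

    for (nm in names(par)) {
      g <- grads[[nm]]
      mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
      vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
      mhat <- mstate[[nm]] / (1 - beta1^epoch)
      vhat <- vstate[[nm]] / (1 - beta2^epoch)
      decay <- if (nm %in% c("W1", "Wc", "Wl", "Wo")) spec$weight_decay else 0
      par[[nm]] <- par[[nm]] - spec$lr * (mhat / (sqrt(vhat) + eps) +
                                            decay * par[[nm]])
    }
    if (!is.finite(train_loss))
      stop("training diverged (loss is not finite); lower spec$lr")
    val_loss <- mean((encoder_forward(par, Xf, cva, K,
                                      rows = needed)$Y - Yva)^2)
    history <- rbind(history, data.frame(epoch = epoch, train = train_loss,
                                         val = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, train_loss,
                      val_loss))
    if (val_loss < best$loss - 1e-8) {
      best <- list(loss = val_loss, par = par, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(
    list(par = best$par, spec = spec, mu = mu, sd = sd_, fps = fps,
         dt = dt, t0 = rates$t0, split = split, seed = seed,
         history = history, best_epoch = best$epoch,
         val_loss = best$loss, unit_ids = rates$unit_ids),
    class = "behavior_encoder")
}

#' @export
print.behavior_encoder <- function(x, ...) {
  cat(sprintf(
    "<behavior_encoder: %d inputs -> %d hidden -> conv(%d x %d) -> %d latents -> %d units; best epoch %d, val MSE %.4f>\n",
    length(x$mu), x$spec$hidden, x$spec$kernel, x$spec$conv_channels,
    x$spec$latent, ncol(x$par$Wo), x$best_epoch, x$val_loss))
  invisible(x)
}

#' Direct predictions and latents of a fitted encoder
#'
#' @param object a `behavior_encoder`.
#' @param behavior behaviour input (as in [train_encoder()]).
#' @param bin_times bin-centre times (seconds) at which to evaluate.
#' @param ... unused.
#' @return list with `pred` (`units x bins`, Hz) and `latents`
#'   (`latent x bins`).
#' @export
predict.behavior_encoder <- function(object, behavior, bin_times, ...) {
  X <- if (inherits(behavior, "behavior_streams"))
    rbind(behavior$x_movie, behavior$x_motion) else behavior
  Xf <- t(X)
  Xf <- sweep(sweep(Xf, 2, object$mu, `-`), 2, object$sd, `/`)
  centres <- pmin(pmax(round((bin_times - object$t0) * object$fps + 0.5), 1L),
                  nrow(Xf))
  fw <- encoder_forward(object$par, Xf, centres, object$spec$kernel)
  list(pred = t(fw$Y), latents = t(fw$Lat))
}

#' Nearest-neighbour prediction from encoder latents
#'
#' For each test-time latent the `k` nearest training latents (Euclidean
#' distance; ties broken by earlier time index) are found and the *recorded*
#' neural activity at those training times is averaged to form the test
#' prediction.
#'
#' @param train_latents `latent x n_train` matrix.
#' @param train_rates recorded activity `units x n_train` (Hz).
#' @param test_latents `latent x n_test` matrix.
#' @param k neighbours to average (50; clipped with a warning if it exceeds
#'   the number of training points).
#' @return `units x n_test` prediction matrix.
#' @export
nn_latent_predict <- function(train_latents, train_rates, test_latents,
                              k = 50) {
  n_train <- ncol(train_latents)
  if (k > n_train) {
    warning("k = ", k, " exceeds ", n_train, " training points; clipped")
    k <- n_train
  }
  # squared Euclidean distances via the expansion |a-b|^2 = |a|^2+|b|^2-2a.b
  d2 <- outer(colSums(test_latents^2), colSums(train_latents^2), `+`) -
    2 * crossprod(test_latents, train_latents)
  n_test <- ncol(test_latents)
  pred <- matrix(0, nrow(train_rates), n_test)
  for (i in seq_len(n_test)) {
    ord <- order(d2[i, ], seq_len(n_train))[seq_len(k)]
    pred[, i] <- rowMeans(train_rates[, ord, drop = FALSE])
  }
  pred
}

#' Residuals of the nearest-neighbour prediction, with window summaries
#'
#' The residual is defined bin-wise as recorded minus nearest-neighbour
#' prediction (positive = the behaviour model underpredicts). Summaries are
#' per-unit means over the pre-laser window (0.8 s before onset), the
#' laser-onset window (first 0.8 s), and the syncope windows.
#'
#' @param recorded,nn_pred `units x n_test` matrices on the same grid.
#' @param bin_times test bin-centre times in seconds.
#' @param lasers laser event table (or onset vector).
#' @param syncope syncope event table (`onset`, `offset`) or NULL.
#' @param onset_window,pre_window window lengths in seconds.
#' @param unit_ids,regions optional unit annotations carried through.
#' @return object of class `encoding_result`: `residual` matrix plus a
#'   `summaries` data.frame (per unit: `pre_laser`, `laser_onset`, `syncope`,
#'   per-laser onset means in `onset_by_laser`).
#' @export
compute_residuals <- function(recorded, nn_pred, bin_times, lasers,
                              syncope = NULL, onset_window = 0.8,
                              pre_window = 0.8, unit_ids = NULL,
                              regions = NULL) {
  stopifnot(identical(dim(recorded), dim(nn_pred)),
            ncol(recorded) == length(bin_times))
  residual <- recorded - nn_pred
  onsets <- if (is.data.frame(lasers)) lasers$onset else as.numeric(lasers)
  win_cols <- function(lo, hi) which(bin_times >= lo & bin_times < hi)
  mean_over <- function(cols) {
    if (!length(cols)) return(rep(NA_real_, nrow(residual)))
    rowMeans(residual[, cols, drop = FALSE])
  }
  miss <- vapply(onsets, function(on)
    length(win_cols(on, on + onset_window)) == 0 ||
      length(win_cols(on - pre_window, on)) == 0, logical(1))
  if (any(miss))
    stop_validation("residuals are only defined on test segments; windows of ",
                    sum(miss), " laser(s) fall outside them")
  onset_by_laser <- vapply(onsets, function(on)
    mean_over(win_cols(on, on + onset_window)), numeric(nrow(residual)))
  pre_by_laser <- vapply(onsets, function(on)
    mean_over(win_cols(on - pre_window, on)), numeric(nrow(residual)))
  onset_by_laser <- matrix(onset_by_laser, nrow = nrow(residual))
  pre_by_laser <- matrix(pre_by_laser, nrow = nrow(residual))
  sync_mean <- rep(NA_real_, nrow(residual))
  if (!is.null(syncope) && nrow(syncope)) {
    cols <- unlist(lapply(seq_len(nrow(syncope)), function(i)
      win_cols(syncope$onset[i],
               ifelse(is.na(syncope$offset[i]), syncope$onset[i] + 4,
                      syncope$offset[i]))))
    sync_mean <- mean_over(cols)
  }
  summaries <- data.frame(
    unit_id = unit_ids %||% paste0("unit", seq_len(nrow(residual))),
    region = regions %||% NA_character_,
    pre_laser = rowMeans(pre_by_laser),
    laser_onset = rowMeans(onset_by_laser),
    syncope = sync_mean)
  structure(
    list(residual = residual, bin_times = bin_times,
         onset_by_laser = onset_by_laser, pre_by_laser = pre_by_laser,
         summaries = summaries, onset_window = onset_window,
         pre_window = pre_window),
    class = "encoding_result")
}

#' Variance explained and 1-s binned correlations of predictions
#'
#' @param recorded,predicted `units x bins` matrices (Hz) on the test grid.
#' @param bin_times bin-centre times in seconds.
#' @param split a split plan (control vs laser test segments).
#' @param dt rate bin width in seconds.
#' @return `data.frame` per unit: `ve_control` (variance explained on the
#'   control segment), `r_control`, `r_stim` (Pearson r of 1-s binned
#'   predicted vs recorded). Zero-variance units get NA.
#' @export
model_metrics <- function(recorded, predicted, bin_times, split, dt = 0.1) {
  roles <- split_bin_roles(split, bin_times)
  ctrl <- which(roles == "test_control")
  stim <- which(roles == "test_laser")
  agg_1s <- function(m, cols) {
    sec <- floor(bin_times[cols])
    t(apply(m[, cols, drop = FALSE], 1, function(v)
      tapply(v, sec, mean)))
  }
  ve <- rep(NA_real_, nrow(recorded))
  if (length(ctrl)) {
    for (u in seq_len(nrow(recorded))) {
      y <- recorded[u, ctrl]; p <- predicted[u, ctrl]
      vy <- stats::var(y)
      if (is.finite(vy) && vy > 0) ve[u] <- 1 - mean((y - p)^2) / vy
    }
  }
  cor_safe <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  r_ctrl <- r_stim <- rep(NA_real_, nrow(recorded))
  if (length(ctrl)) {
    Ra <- agg_1s(recorded, ctrl); Pa <- agg_1s(predicted, ctrl)
    r_ctrl <- vapply(seq_len(nrow(recorded)), function(u)
      cor_safe(Ra[u, ], Pa[u, ]), numeric(1))
  }
  if (length(stim)) {
    Ra <- agg_1s(recorded, stim); Pa <- agg_1s(predicted, stim)
    r_stim <- vapply(seq_len(nrow(recorded)), function(u)
      cor_safe(Ra[u, ], Pa[u, ]), numeric(1))
  }
  data.frame(unit = seq_len(nrow(recorded)), ve_control = ve,
             r_control = r_ctrl, r_stim = r_stim)
}

#' Run the full encoding stage on a session
#'
#' Bins the curated units, builds the split, trains the encoder, forms direct
#' and nearest-neighbour predictions on the test segments, and returns the
#' residual analysis plus metrics for both prediction routes.
#'
#' @param ses a [session] with behaviour streams and units.
#' @param spec an [encoder_spec()].
#' @param k neighbours for the latent prediction (50).
#' @param seed seed (split assignment and weight init).
#' @param syncope optional syncope table for residual summaries (defaults to
#'   `ses$syncope`).
#' @return list with `model`, `split`, `result` (an `encoding_result`),
#'   `metrics_nn`, `metrics_direct`, `recorded`, `nn_pred`, `direct_pred`,
#'   `test_bins`, `bin_times`.
#' @export
encode_session <- function(ses, spec = encoder_spec(), k = 50, seed = 1,
                           syncope = NULL) {
  stopifnot(inherits(ses, "session"))
  if (is.null(ses$behavior)) stop_validation("session has no behaviour streams")
  if (!length(ses$units)) stop_validation("session has no units")
  duration <- max(vapply(ses$streams, function(s)
    s$t0 + ts_duration(s), numeric(1)),
    ncol(ses$behavior$x_movie) / ses$behavior$sample_rate)
  rates <- bin_rates(ses$units, dt = 0.1, t0 = 0, t_end = duration)
  split <- make_split(duration, ses$lasers, seed = seed)
  model <- train_encoder(ses$behavior, rates, split, spec, seed = seed)
  roles <- split_bin_roles(split, rates$bin_times)
  test <- which(roles %in% c("test_laser", "test_control"))
  train <- which(roles == "train")
  pr_test <- predict(model, ses$behavior, rates$bin_times[test])
  pr_train <- predict(model, ses$behavior, rates$bin_times[train])
  recorded_all <- rates$counts / rates$dt
  recorded <- recorded_all[, test, drop = FALSE]
  nn_pred <- nn_latent_predict(pr_train$latents,
                               recorded_all[, train, drop = FALSE],
                               pr_test$latents, k = k)
  syncope <- syncope %||% ses$syncope
  result <- compute_residuals(recorded, nn_pred, rates$bin_times[test],
                              ses$lasers, syncope,
                              unit_ids = rates$unit_ids,
                              regions = rates$regions)
  metrics_nn <- model_metrics(recorded, nn_pred, rates$bin_times[test], split)
  metrics_direct <- model_metrics(recorded, pr_test$pred,
                                  rates$bin_times[test], split)
  list(model = model, split = split, result = result,
       metrics_nn = metrics_nn, metrics_direct = metrics_direct,
       recorded = recorded, nn_pred = nn_pred, direct_pred = pr_test$pred,
       test_bins = test, bin_times = rates$bin_times[test],
       unit_ids = rates$unit_ids, regions = rates$regions)
}
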