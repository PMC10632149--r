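# Unit curation, rate binning, Poisson inactivity statistics at syncope
# onset, laser-response latency (Poisson tail probability), activation
# classification, and per-region aggregation.

#' Flag drifting units
#'
#' Each unit's firing rate in 100-ms bins is smoothed with a Gaussian of
#' sigma = 30 s; a unit whose smoothed rate varies by more than a factor of 5
#' over the recording is flagged as drifting. The minimum rate is floored at
#' `eps` (1e-3 Hz) so units that fall fully silent for a stretch flag.
#'
#' @param units list of [spike_train].
#' @param duration recording duration in seconds (> 60).
#' @param bin_width rate bin width in seconds (0.1).
#' @param sigma Gaussian smoothing width in seconds, read as the standard
#'   deviation (30).
#' @param factor_threshold max/min ratio above which a unit drifts (5).
#' @param eps rate floor in Hz for the ratio denominator.
#' @return logical vector, one flag per unit (`NA` for empty spike trains,
#'   which are handled by the low-rate filter instead).
#' @export
flag_drifting_units <- function(units, duration, bin_width = 0.1, sigma = 30,
                                factor_threshold = 5, eps = 1e-3) {
  if (duration <= 60) stop_validation("drift screening needs > 60 s of data")
  nb <- ceiling(duration / bin_width)
  vapply(units, function(u) {
    if (!length(u$spike_times)) return(NA)
    counts <- tabulate(bin_index(u$spike_times, 0, bin_width), nbins = nb)
    rate <- gaussian_smooth(counts / bin_width, sigma / bin_width)
    max(rate) / max(min(rate), eps) > factor_threshold
  }, logical(1))
}

#' Flag low-rate units (session mean rate strictly below 0.25 Hz)
#'
#' @param units list of [spike_train].
#' @param duration recording duration in seconds.
#' @param threshold exclusion rate in Hz; the rule is strict `< threshold`, so
#'   a unit at exactly 0.25 Hz is retained.
#' @return logical vector of flags.
#' @export
flag_low_rate_units <- function(units, duration, threshold = 0.25) {
  vapply(units, function(u)
    length(u$spike_times) / duration < threshold, logical(1))
}

#' Bin spike trains into a units x bins count matrix
#'
#' Half-open bins `[t, t + dt)`: a spike exactly at a bin edge counts in the
#' later bin.
#'
#' @param units list of [spike_train] (curated).
#' @param dt bin width in seconds (0.1 = the 10-Hz rate grid).
#' @param t0 time of the first bin edge.
#' @param t_end end of the binned extent; defaults to the last spike rounded
#'   up to a full bin.
#' @return object of class `binned_rates`: list with `counts` (units x bins),
#'   `dt`, `t0`, `unit_ids`, `regions`, and `bin_times` (bin centres).
#' @export
bin_rates <- function(units, dt = 0.1, t0 = 0, t_end = NULL) {
  if (is.null(t_end))
    t_end <- max(vapply(units, function(u)
      if (length(u$spike_times)) max(u$spike_times) else 0, numeric(1)))
  nb <- max(1L, ceiling((t_end - t0) / dt - 1e-9))
  counts <- t(vapply(units, function(u) {
    st <- u$spike_times[u$spike_times >= t0 & u$spike_times < t0 + nb * dt]
    tabulate(bin_index(st, t0, dt), nbins = nb)
  }, integer(nb)))
  structure(
    list(counts = counts, dt = dt, t0 = t0,
         unit_ids = vapply(units, `[[`, "", "unit_id"),
         regions = vapply(units, `[[`, "", "region"),
         bin_times = t0 + (seq_len(nb) - 0.5) * dt),
    class = "binned_rates")
}

#' @export
print.binned_rates <- function(x, ...) {
  cat(sprintf("<binned_rates: %d units x %d bins of %g s>\n",
              nrow(x$counts), ncol(x$counts), x$dt))
  invisible(x)
}

#' Silence length required to call a Poisson unit inactive
#'
#' Under Poisson spiking at rate lambda the probability of no spikes in `k`
#' bins of width `dt` is `exp(-lambda * k * dt)`. Setting that probability to
#' `P0` gives `k = -ln(P0) / (lambda * dt)`, capped at `k_max` bins for
#' low-rate units.
#'
#' @param lambda firing rate(s) in Hz (> 0), vectorized.
#' @param P0 chance probability of the silent period (0.01).
#' @param dt bin width in seconds (0.001).
#' @param k_max cap in bins (4000, i.e. 4 s).
#' @return integer bin count(s) `k`.
#' @export
inactivity_bins_required <- function(lambda, P0 = 0.01, dt = 0.001,
                                     k_max = 4000) {
  if (any(lambda <= 0)) stop_validation("lambda must be > 0 (exclude silent units upstream)")
  if (P0 <= 0 || P0 > 1) stop_validation("P0 must be in (0, 1]")
  pmin(as.integer(ceiling(-log(P0) / (lambda * dt) - 1e-9)), as.integer(k_max))
}

# Inter-spike silent gaps of a train inside [extent_lo, extent_hi], including
# the leading and trailing gaps. Returns matrix with columns start, end.
silent_gaps <- function(spike_times, extent_lo, extent_hi) {
  st <- spike_times[spike_times >= extent_lo & spike_times <= extent_hi]
  starts <- c(extent_lo, st)
  ends <- c(st, extent_hi)
  cbind(start = starts, end = ends)
}

#' Is a unit inactive at syncope onset, and for what fraction of the bout?
#'
#' A unit is inactive at syncope onset if some silent stretch of at least `k`
#' 1-ms bins (with `k` from [inactivity_bins_required()], so the stretch has
#' chance probability below `P0` under the unit's baseline Poisson rate)
#' starts within `onset_tolerance` of the syncope onset. Any admissible start
#' point inside an inter-spike gap counts, i.e. the criterion asks whether a
#' sufficiently improbable silence is time-locked to the onset. `time_off` is
#' the fraction of the syncope window's 1-ms bins lying inside qualifying
#' silent gaps, computed only for flagged units.
#'
#' @param unit a [spike_train] with a finite `baseline_rate` (> 0).
#' @param syncope one row of a syncope event table (needs `onset`, `offset`;
#'   an `NA` offset falls back to `window_end`).
#' @param params list with `P0`, `dt`, `k_max`, `onset_tolerance` (defaults
#'   0.01 / 0.001 / 4000 / 0.25); see [inactivity_bins_required()].
#' @param extent recording extent `c(lo, hi)` in seconds; the syncope window
#'   is truncated to it with a warning if needed.
#' @param window_end end of the syncope window when `offset` is undefined
#'   (typically the laser end).
#' @return list with `inactive` (flag), `time_off` (fraction or NA), `k`.
#' @export
inactive_at_syncope <- function(unit, syncope, params = list(), extent,
                                window_end = NULL) {
  p <- utils::modifyList(
    list(P0 = 0.01, dt = 0.001, k_max = 4000, onset_tolerance = 0.25), params)
  lam <- unit$baseline_rate
  if (is.na(lam) || lam <= 0)
    stop_validation("unit ", unit$unit_id, " has no usable baseline rate")
  k <- inactivity_bins_required(lam, p$P0, p$dt, p$k_max)
  need <- k * p$dt
  onset <- syncope$onset
  w_end <- if (!is.na(syncope$offset %||% NA_real_)) syncope$offset else
    window_end %||% (onset + 4)
  if (w_end > extent[2] || onset < extent[1]) {
    warning("syncope window extends beyond the recording; truncating")
    w_end <- min(w_end, extent[2])
    onset <- max(onset, extent[1])
  }
  gaps <- silent_gaps(unit$spike_times, extent[1], extent[2])
  len <- gaps[, "end"] - gaps[, "start"]
  ok <- len >= need
  tol_lo <- onset - p$onset_tolerance
  tol_hi <- onset + p$onset_tolerance
  # a qualifying silence can start anywhere in [gap_start, gap_end - need]
  flag <- any(ok & (gaps[, "start"] <= tol_hi) &
                ((gaps[, "end"] - need) >= tol_lo))
  time_off <- NA_real_
  if (flag && w_end > onset) {
    qual <- gaps[ok, , drop = FALSE]
    covered <- pmax(0, pmin(qual[, "end"], w_end) - pmax(qual[, "start"], onset))
    time_off <- min(1, sum(covered) / (w_end - onset))
  }
  list(inactive = flag, time_off = time_off, k = k)
}

#' Inactivity counts at a random control window
#'
#' Applies the syncope inactivity criterion at random onsets drawn from
#' laser-free, syncope-free baseline spans, and compares per-region
#' percentages of inactive units between the syncope onset and the control
#' window with a paired t-test across regions (regions are the pairs).
#'
#' @param units list of [spike_train] with baseline rates.
#' @param syncope syncope event table (first row is used for the comparison).
#' @param duration recording duration in seconds.
#' @param lasers laser event table or NULL.
#' @param params see [inactive_at_syncope()].
#' @param n_draws number of random control onsets averaged per unit.
#' @param margin seconds to keep clear of laser/syncope periods.
#' @param seed RNG seed.
#' @return list with `table` (per region: `n_units`, `n_inactive_syncope`,
#'   `pct_inactive_syncope`, `mean_inactive_control`, `pct_inactive_control`)
#'   and `t_test` (paired across regions, or NULL with < 2 regions).
#' @export
random_window_control <- function(units, syncope, duration, lasers = NULL,
                                  params = list(), n_draws = 1, margin = 5,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  busy <- rbind(
    if (!is.null(lasers) && nrow(lasers))
      cbind(lasers$onset - margin, lasers$onset + lasers$duration + margin),
    if (!is.null(syncope) && nrow(syncope))
      cbind(syncope$onset - margin,
            ifelse(is.na(syncope$offset), syncope$onset + 30, syncope$offset) + margin))
  eligible <- function(t) is.null(busy) || !any(t >= busy[, 1] & t <= busy[, 2])
  draw_onset <- function() {
    for (i in 1:1000) {
      t <- stats::runif(1, margin, duration - margin)
      if (eligible(t)) return(t)
    }
    stop("no eligible baseline span for a control window")
  }
  extent <- c(0, duration)
  syn_row <- syncope[1, , drop = FALSE]
  syn_flag <- vapply(units, function(u)
    inactive_at_syncope(u, syn_row, params, extent)$inactive, logical(1))
  ctl_frac <- vapply(units, function(u) {
    hits <- 0
    for (d in seq_len(n_draws)) {
      on <- draw_onset()
      fake <- data.frame(onset = on, offset = NA_real_)
      hits <- hits + inactive_at_syncope(u, fake, params, extent,
                                         window_end = min(on + 4, duration))$inactive
    }
    hits / n_draws
  }, numeric(1))
  regions <- vapply(units, `[[`, "", "region")
  tab <- do.call(rbind, lapply(split(seq_along(units), regions), function(ix) {
    data.frame(region = regions[ix[1]], n_units = length(ix),
               n_inactive_syncope = sum(syn_flag[ix]),
               pct_inactive_syncope = 100 * mean(syn_flag[ix]),
               mean_inactive_control = mean(ctl_frac[ix]),
               pct_inactive_control = 100 * mean(ctl_frac[ix]))
  }))
  rownames(tab) <- NULL
  tt <- if (nrow(tab) >= 2L)
    stats::t.test(tab$pct_inactive_syncope, tab$pct_inactive_control,
                  paired = TRUE) else NULL
  list(table = tab, t_test = tt)
}

#' Poisson tail probability of a laser response
#'
#' Probability of observing at least `n` spikes pooled over `N` repetitions of
#' a window of length `t`, under baseline Poisson rate `lambda`:
#' `P = 1 - sum_{m=0}^{n-1} (N lambda t)^m exp(-N lambda t) / m!`,
#' accumulated in log space so large `N lambda t` cannot overflow.
#'
#' @param n observed spike count (>= 0).
#' @param lambda baseline rate in Hz.
#' @param N number of repetitions.
#' @param t window length in seconds (> 0).
#' @return probability in `[0, 1]`.
#' @export
response_probability <- function(n, lambda, N, t) {
  if (n < 0) stop_validation("n must be >= 0")
  if (t <= 0) stop_validation("t must be > 0")
  if (n == 0) return(1)
  mu <- N * lambda * t
  if (mu == 0) return(0)
  m <- 0:(n - 1)
  logcdf <- logsumexp(m * log(mu) - mu - lgamma(m + 1))
  p <- -expm1(min(logcdf, 0))
  min(max(p, 0), 1)
}

#' Latency of a unit's response to laser onset
#'
#' Windows `[onset, onset + t)` grow from `t = step` in 1-ms steps; at each
#' step the pooled spike count over the `N` aligned onsets is compared with
#' the baseline Poisson expectation via [response_probability()]. The latency
#' is the first `t` at which the probability falls below `p_threshold`
#' (default 1e-6); `NA` if it never does within `max_t`.
#'
#' @param unit a [spike_train] with a finite `baseline_rate`.
#' @param onsets laser onset times in seconds (N repetitions).
#' @param p_threshold chance-probability threshold (1e-6).
#' @param step window increment in seconds (0.001).
#' @param max_t largest window searched in seconds (default 1).
#' @return latency in seconds, or `NA_real_`.
#' @export
laser_latency <- function(unit, onsets, p_threshold = 1e-6, step = 0.001,
                          max_t = 1) {
  lam <- unit$baseline_rate
  if (is.na(lam) || lam < 0) stop_validation("unit needs a baseline rate")
  N <- length(onsets)
  if (N < 1L) stop_validation("need at least one laser onset")
  nsteps <- round(max_t / step)
  rel <- unlist(lapply(onsets, function(on) {
    d <- unit$spike_times - on
    d[d >= 0 & d < max_t]
  }))
  if (!length(rel)) return(NA_real_)
  counts <- cumsum(tabulate(bin_index(rel, 0, step), nbins = nsteps))
  # log-space survival probability per step (own accumulation; ppois is the
  # independent oracle in the tests)
  pv <- vapply(seq_len(nsteps), function(i) {
    response_probability(counts[i], lam, N, i * step)
  }, numeric(1))
  hit <- which(pv < p_threshold)
  if (!length(hit)) return(NA_real_)
  hit[1] * step
}

#' Classify one unit as laser-activated from its prediction residuals
#'
#' Three criteria, all required: (1) the behaviour-prediction residual
#' averaged over the laser-onset windows (first `onset_window` seconds after
#' each onset) across all stimulations is strictly positive; (2) the
#' onset-window residual strictly exceeds the pre-laser-window residual for
#' every stimulation; (3) the unit responded with latency below
#' `activation_latency_max`.
#'
#' @param residual residual trace of the unit on the rate grid (test bins).
#' @param bin_times bin-centre times of `residual` in seconds.
#' @param laser_onsets laser onset times (all must lie in test segments).
#' @param latency unit latency from [laser_latency()] (seconds or NA).
#' @param onset_window,pre_window window lengths in seconds (0.8 / 0.8).
#' @param activation_latency_max latency cut-off in seconds (0.25).
#' @return list with `criterion1`, `criterion2`, `criterion3`, `activated`.
#' @export
classify_laser_activated <- function(residual, bin_times, laser_onsets,
                                     latency, onset_window = 0.8,
                                     pre_window = 0.8,
                                     activation_latency_max = 0.25) {
  if (!length(laser_onsets)) stop_validation("need at least one laser onset")
  win_mean <- function(lo, hi) {
    sel <- bin_times >= lo & bin_times < hi
    if (!any(sel)) return(NA_real_)
    mean(residual[sel])
  }
  on_means <- vapply(laser_onsets, function(on)
    win_mean(on, on + onset_window), numeric(1))
  pre_means <- vapply(laser_onsets, function(on)
    win_mean(on - pre_window, on), numeric(1))
  if (anyNA(on_means) || anyNA(pre_means))
    stop_validation("residuals do not cover all laser onset/pre windows")
  c1 <- mean(on_means) > 0
  c2 <- all(on_means > pre_means)
  c3 <- !is.na(latency) && latency < activation_latency_max
  list(criterion1 = c1, criterion2 = c2, criterion3 = c3,
       activated = c1 && c2 && c3)
}

#' Per-region summary of unit classifications
#'
#' @param classifications `data.frame` with one row per unit: `unit_id`,
#'   `region`, `latency`, `laser_activated`, `inactive_at_syncope`,
#'   `time_off` (as produced by [run_pipeline()]).
#' @return `data.frame` per region: unit counts, number activated, median
#'   latency of activated units, percentage inactive at syncope, mean time
#'   off of inactive units; ordered by median latency.
#' @export
region_summary <- function(classifications) {
  stopifnot(nrow(classifications) >= 1L)
  out <- do.call(rbind, lapply(
    split(classifications, classifications$region), function(g) {
      act <- g[!is.na(g$laser_activated) & g$laser_activated, , drop = FALSE]
      inact <- g$inactive_at_syncope
      data.frame(
        region = g$region[1],
        n_units = nrow(g),
        n_activated = nrow(act),
        median_latency = if (nrow(act)) stats::median(act$latency) else NA_real_,
        pct_inactive = if (all(is.na(inact))) NA_real_ else
          100 * mean(inact, na.rm = TRUE),
        mean_time_off = if (all(is.na(g$time_off))) NA_real_ else
          mean(g$time_off, na.rm = TRUE))
    }))
  out <- out[order(out$median_latency), , drop = FALSE]
  rownames(out) <- NULL
  out
}
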