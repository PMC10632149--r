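#' Atlas-style brain-region labels accepted by default
#'
#' Region grouping follows the Allen CCF-derived labels used for probe
#' localization; free-form labels can be allowed by passing a custom
#' vocabulary to [spike_train()].
#' @export
default_regions <- c(
  "PVZ", "BMA", "ACA", "AI", "BLA", "BST", "DORpm", "DORsm", "HPC", "ILA",
  "LA", "LS", "LZ", "MBmot", "MEZ", "OLF", "PALd", "PALm", "PIR", "PL",
  "SSp", "SSs", "STRd", "STRv", "VISC", "PTLp")

#' Sorted spike train of one curated unit
#'
#' @param unit_id unit identifier (string).
#' @param region brain-region label; validated against `vocabulary`.
#' @param spike_times spike times in seconds, strictly increasing.
#' @param baseline_rate mean firing rate in Hz excluding encoding-model test
#'   segments (the lambda of the Poisson statistics); NA until computed.
#' @param vocabulary allowed region labels (default [default_regions]).
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(unit_id, region, spike_times, baseline_rate = NA_real_,
                        vocabulary = default_regions) {
  region <- as.character(region)
  if (!nzchar(region)) stop_validation("region label must be non-empty")
  if (!is.null(vocabulary) && !(region %in% vocabulary))
    stop_validation("unknown region label '", region, "'")
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE) && length(spike_times) > 1L)
    stop_validation("spike_times must be strictly increasing (unit ", unit_id, ")")
  if (!is.na(baseline_rate) && baseline_rate < 0)
    stop_validation("baseline_rate must be >= 0")
  structure(
    list(unit_id = as.character(unit_id), region = region,
         spike_times = spike_times, baseline_rate = baseline_rate),
    class = "spike_train")
}

#' Laser stimulation event table
#'
#' @param onset onset times in seconds.
#' @param duration stimulus durations in seconds (> 0).
#' @param pulse_hz pulse train frequency in Hz (typically 5, 10 or 20).
#' @param pulse_width pulse width in seconds (0.02 typical).
#' @param pattern `"continuous"` or `"5s_on_off"`.
#' @return a `data.frame` with one row per stimulation, sorted by onset.
#' @export
laser_events <- function(onset, duration, pulse_hz = 20, pulse_width = 0.02,
                         pattern = "continuous") {
  n <- length(onset)
  ev <- data.frame(onset = as.numeric(onset),
                   duration = rep_len(as.numeric(duration), n),
                   pulse_hz = rep_len(as.numeric(pulse_hz), n),
                   pulse_width = rep_len(as.numeric(pulse_width), n),
                   pattern = rep_len(as.character(pattern), n))
  if (any(ev$onset < 0)) stop_validation("laser onsets must be >= 0")
  if (any(ev$duration <= 0)) stop_validation("laser durations must be > 0")
  if (!all(ev$pattern %in% c("continuous", "5s_on_off")))
    stop_validation("pattern must be 'continuous' or '5s_on_off'")
  ev <- ev[order(ev$onset), , drop = FALSE]
  if (n > 1L && any(ev$onset[-1] < (ev$onset + ev$duration)[-n]))
    stop_validation("laser events must not overlap")
  rownames(ev) <- NULL
  ev
}

#' Analysis window on the session clock
#'
#' @param start,end window bounds in seconds (`end > start`).
#' @param role one of `pre_laser`, `laser_onset`, `syncope_onset`, `stim`,
#'   `post_stim`, `baseline`, `control`.
#' @export
analysis_window <- function(start, end, role = "baseline") {
  roles <- c("pre_laser", "laser_onset", "syncope_onset", "stim",
             "post_stim", "baseline", "control")
  role <- match.arg(role, roles)
  if (end <= start) stop_validation("analysis window needs end > start")
  structure(list(start = start, end = end, role = role),
            class = "analysis_window")
}

#' Session container binding all per-recording streams on one clock
#'
#' @param id session identifier.
#' @param streams named list of [time_series] (continuous channels).
#' @param units list of [spike_train].
#' @param behavior behaviour stream bundle (see [behavior_streams]).
#' @param lasers laser event table from [laser_events()] (or NULL).
#' @param syncope syncope event table (filled in by the spectral stage).
#' @param metadata named list of free-form metadata.
#' @return an object of class `session`.
#' @export
session <- function(id, streams = list(), units = list(), behavior = NULL,
                    lasers = NULL, syncope = NULL, metadata = list()) {
  stopifnot(is.list(streams), is.list(units))
  for (s in streams) {
    stopifnot(inherits(s, "time_series"))
    if (s$t0 < 0) stop_validation("stream t0 < 0: clock mismatch")
  }
  for (u in units) stopifnot(inherits(u, "spike_train"))
  structure(
    list(id = as.character(id), streams = streams, units = units,
         behavior = behavior, lasers = lasers, syncope = syncope,
         metadata = metadata),
    class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session '%s': %d stream(s), %d unit(s), %d laser(s)%s>\n",
              x$id, length(x$streams), length(x$units),
              if (is.null(x$lasers)) 0L else nrow(x$lasers),
              if (is.null(x$behavior)) "" else ", behaviour"))
  invisible(x)
}

#' Behaviour stream bundle at the video frame rate
#'
#' All behaviour streams share one 30-Hz clock (config) with `T` frames.
#'
#' @param x_movie,x_motion matrices `n_components x T` of movie / motion-energy
#'   SVD projections.
#' @param whisker_motion_svd matrix `>= 10 x T` of whisker-pad motion SVD
#'   components.
#' @param keypoints numeric array `4 x 2 x T` of pupil keypoints, rows named
#'   `top`, `bottom`, `left`, `right`, columns `x`, `y`.
#' @param confidence matrix `4 x T` of per-keypoint tracking likelihoods.
#' @param eye_dark_pixel_count per-frame count of eye-ROI pixels darker than
#'   the saturation threshold (used for blink detection).
#' @param sample_rate frame rate in Hz (30 by default).
#' @param t0 time of the first frame in seconds.
#' @export
behavior_streams <- function(x_movie = NULL, x_motion = NULL,
                             whisker_motion_svd = NULL, keypoints = NULL,
                             confidence = NULL, eye_dark_pixel_count = NULL,
                             sample_rate = 30, t0 = 0) {
  lens <- c(
    if (!is.null(x_movie)) ncol(x_movie),
    if (!is.null(x_motion)) ncol(x_motion),
    if (!is.null(whisker_motion_svd)) ncol(whisker_motion_svd),
    if (!is.null(keypoints)) dim(keypoints)[3],
    if (!is.null(confidence)) ncol(confidence),
    if (!is.null(eye_dark_pixel_count)) length(eye_dark_pixel_count))
  if (length(unique(lens)) > 1L)
    stop_validation("behaviour streams disagree on frame count")
  structure(
    list(x_movie = x_movie, x_motion = x_motion,
         whisker_motion_svd = whisker_motion_svd, keypoints = keypoints,
         confidence = confidence, eye_dark_pixel_count = eye_dark_pixel_count,
         sample_rate = sample_rate, t0 = t0),
    class = "behavior_streams")
}

# ---------------------------------------------------------------------------
# Bundle I/O: directory of CSV tables + JSON manifest. Layout:
#   <path>/manifest.json             id, metadata, stream/behaviour metadata
#   <path>/lasers.csv                onset_s,duration_s,pulse_hz,pulse_width_s,pattern
#   <path>/units.csv                 unit_id,region,spike_time_s
#   <path>/unit_table.csv            unit_id,region,baseline_rate_hz
#   <path>/syncope.csv               onset_s,offset_s,laser_onset_s,source
#   <path>/streams/<name>.csv        single `value` column
#   <path>/behavior/*.csv            matrices (rows = components), keypoints long
# ---------------------------------------------------------------------------

write_matrix_csv <- function(m, path) {
  dt <- data.table::as.data.table(m)
  data.table::setnames(dt, paste0("c", seq_len(ncol(dt))))
  data.table::fwrite(dt, path)
}

read_matrix_csv <- function(path) {
  as.matrix(data.table::fread(path))
}

#' Save a session bundle (CSV tables + JSON manifest)
#'
#' The write is deterministic: identical sessions produce byte-identical
#' bundles (fixed key and file ordering, fixed numeric formatting).
#'
#' @param x a [session].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_session <- function(x, path) {
  stopifnot(inherits(x, "session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle directory ", path)

  streams_meta <- list()
  if (length(x$streams)) {
    dir.create(file.path(path, "streams"), showWarnings = FALSE)
    for (nm in sort(names(x$streams))) {
      s <- x$streams[[nm]]
      data.table::fwrite(data.table::data.table(value = s$values),
                         file.path(path, "streams", paste0(nm, ".csv")))
      streams_meta[[nm]] <- list(sample_rate = s$sample_rate, t0 = s$t0,
                                 label = s$label)
    }
  }

  if (length(x$units)) {
    rows <- lapply(x$units, function(u)
      if (length(u$spike_times))
        data.table::data.table(unit_id = u$unit_id, region = u$region,
                               spike_time_s = u$spike_times))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    spikes <- if (length(rows)) data.table::rbindlist(rows) else
      data.table::data.table(unit_id = character(), region = character(),
                             spike_time_s = numeric())
    data.table::fwrite(spikes, file.path(path, "units.csv"))
    unit_tab <- data.table::data.table(
      unit_id = vapply(x$units, `[[`, "", "unit_id"),
      region = vapply(x$units, `[[`, "", "region"),
      baseline_rate_hz = vapply(x$units, `[[`, 0, "baseline_rate"))
    data.table::fwrite(unit_tab, file.path(path, "unit_table.csv"))
  }

  if (!is.null(x$lasers) && nrow(x$lasers)) {
    lz <- data.table::data.table(
      onset_s = x$lasers$onset, duration_s = x$lasers$duration,
      pulse_hz = x$lasers$pulse_hz, pulse_width_s = x$lasers$pulse_width,
      pattern = x$lasers$pattern)
    data.table::fwrite(lz, file.path(path, "lasers.csv"))
  }

  if (!is.null(x$syncope) && nrow(x$syncope))
    data.table::fwrite(data.table::as.data.table(x$syncope),
                       file.path(path, "syncope.csv"))

  behavior_meta <- NULL
  if (!is.null(x$behavior)) {
    b <- x$behavior
    dir.create(file.path(path, "behavior"), showWarnings = FALSE)
    for (nm in c("x_movie", "x_motion", "whisker_motion_svd")) {
      if (!is.null(b[[nm]]))
        write_matrix_csv(b[[nm]], file.path(path, "behavior", paste0(nm, ".csv")))
    }
    if (!is.null(b$confidence))
      write_matrix_csv(b$confidence, file.path(path, "behavior", "confidence.csv"))
    if (!is.null(b$eye_dark_pixel_count))
      data.table::fwrite(
        data.table::data.table(count = b$eye_dark_pixel_count),
        file.path(path, "behavior", "eye_dark_pixel_count.csv"))
    if (!is.null(b$keypoints)) {
      kp <- b$keypoints
      nT <- dim(kp)[3]
      long <- data.table::data.table(
        frame = rep(seq_len(nT), each = 4L),
        point = rep(c("top", "bottom", "left", "right"), nT),
        x = as.vector(kp[, 1, ]), y = as.vector(kp[, 2, ]))
      data.table::fwrite(long, file.path(path, "behavior", "keypoints.csv"))
    }
    behavior_meta <- list(sample_rate = b$sample_rate, t0 = b$t0)
  }

  manifest <- list(id = x$id, metadata = x$metadata, streams = streams_meta,
                   behavior = behavior_meta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a session bundle written by [save_session()]
#'
#' Missing optional tables (no LDF stream, no behaviour, no lasers) yield
#' empty fields, not errors.
#'
#' @param path bundle directory.
#' @return a [session].
#' @export
load_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a session bundle: missing manifest.json in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$id)) stop("malformed manifest: missing key 'id'")

  streams <- list()
  for (nm in names(manifest$streams)) {
    meta <- manifest$streams[[nm]]
    for (k in c("sample_rate", "t0"))
      if (is.null(meta[[k]]))
        stop("malformed manifest: stream '", nm, "' missing key '", k, "'")
    if (meta$t0 < 0) stop_validation("stream '", nm, "' has t0 < 0: clock mismatch")
    vals <- data.table::fread(file.path(path, "streams", paste0(nm, ".csv")))$value
    streams[[nm]] <- time_series(vals, meta$sample_rate, meta$t0,
                                 meta$label %||% nm, na_ok = TRUE)
  }

  units <- list()
  ut_file <- file.path(path, "unit_table.csv")
  if (file.exists(ut_file)) {
    unit_tab <- data.table::fread(ut_file)
    spikes <- data.table::fread(file.path(path, "units.csv"))
    for (i in seq_len(nrow(unit_tab))) {
      uid <- unit_tab$unit_id[i]
      st <- sort(spikes$spike_time_s[spikes$unit_id == uid])
      units[[length(units) + 1L]] <- spike_train(
        uid, unit_tab$region[i], st,
        baseline_rate = unit_tab$baseline_rate_hz[i], vocabulary = NULL)
    }
  }

  lasers <- NULL
  lf <- file.path(path, "lasers.csv")
  if (file.exists(lf)) {
    lz <- data.table::fread(lf)
    lasers <- laser_events(lz$onset_s, lz$duration_s, lz$pulse_hz,
                           lz$pulse_width_s, lz$pattern)
  }

  syncope <- NULL
  sf <- file.path(path, "syncope.csv")
  if (file.exists(sf)) syncope <- as.data.frame(data.table::fread(sf))

  behavior <- NULL
  bdir <- file.path(path, "behavior")
  if (dir.exists(bdir)) {
    bm <- manifest$behavior
    mats <- list()
    for (nm in c("x_movie", "x_motion", "whisker_motion_svd", "confidence")) {
      f <- file.path(bdir, paste0(nm, ".csv"))
      mats[[nm]] <- if (file.exists(f)) unname(read_matrix_csv(f))
    }
    eye <- NULL
    f <- file.path(bdir, "eye_dark_pixel_count.csv")
    if (file.exists(f)) eye <- data.table::fread(f)$count
    kp <- NULL
    f <- file.path(bdir, "keypoints.csv")
    if (file.exists(f)) {
      long <- data.table::fread(f)
      nT <- max(long$frame)
      kp <- array(NA_real_, dim = c(4, 2, nT),
                  dimnames = list(c("top", "bottom", "left", "right"),
                                  c("x", "y"), NULL))
      ord <- order(long$frame, match(long$point, c("top", "bottom", "left", "right")))
      long <- long[ord]
      kp[, 1, ] <- long$x
      kp[, 2, ] <- long$y
    }
    behavior <- behavior_streams(
      x_movie = mats$x_movie, x_motion = mats$x_motion,
      whisker_motion_svd = mats$whisker_motion_svd, keypoints = kp,
      confidence = mats$confidence, eye_dark_pixel_count = eye,
      sample_rate = bm$sample_rate %||% 30, t0 = bm$t0 %||% 0)
  }

  metadata <- manifest$metadata
  if (length(metadata) == 0L) metadata <- list()
  session(manifest$id, streams = streams, units = units, behavior = behavior,
          lasers = lasers, syncope = syncope, metadata = metadata)
}
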