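#' Default pipeline configuration
#'
#' Every numeric constant of the analysis is a config default, grouped per
#' stage; [run_pipeline()] consumes this structure and
#' [write_config()]/[read_config()] round-trip it through YAML.
#'
#' @return nested named list of class `synckit_config`.
#' @export
default_config <- function() {
  structure(list(
    stages = list(spectral = TRUE, spikes = TRUE, encoding = TRUE,
                  physiology = TRUE),
    seed = 1,
    spectral = list(
      stream = "eeg", notch = c(59, 61), n_wavelets = 80,
      fmin = 0.5, fmax = 120, gamma = 3, beta = 27,
      baseline_pre = 30, window_post = 60, target_rate = 50,
      band = c(8, 100), onset_frac = 0.5, offset_frac = 0.8,
      smooth_window = 1,
      n_perm = 1000, alpha_per_tail = 0.025, cluster_forming_p = 0.05,
      fft_segment = 2, fft_taper = "none"),
    spikes = list(
      drift_bin = 0.1, drift_sigma = 30, drift_factor = 5, drift_eps = 1e-3,
      low_rate_threshold = 0.25, rate_bin = 0.1,
      P0 = 0.01, dt = 0.001, k_max = 4000, onset_tolerance = 0.25,
      p_threshold = 1e-6, latency_step = 0.001, latency_max = 1,
      activation_latency_max = 0.25, onset_window = 0.8, pre_window = 0.8,
      control_window = 0.25),
    encoding = list(
      seg_nontest = 50, seg_test = 63, test_pre = 3, val_frac = 0.2,
      hidden = 64, conv_channels = 32, kernel = 9, latent = 16,
      lr = 2e-3, weight_decay = 1e-4, max_epochs = 100, patience = 8,
      k_neighbours = 50),
    behavior = list(
      n_components = 250, segment_length = 1000, whisk_top = 10,
      median_window = 5, conf_threshold = 0.75, blink_area_threshold = 200,
      laser_baseline = c(-30, 0), laser_summary = c(0, 5),
      syncope_baseline = c(-6, -4), syncope_summary = c(0, 2)),
    physiology = list(
      ecg_band = c(10, 50), resp_band = c(1, 10), smooth_window = 1,
      baseline = 30, hr_stim_window = c(6, 24), hr_post_window = c(30, 60),
      rr_stim_window = c(6, 15), rr_post_window = c(36, 45),
      ldf_baseline = 30, ldf_median_window = 0.5, shift_pbg = 10,
      shift_pe = 40)),
    class = "synckit_config")
}

#' @rdname default_config
#' @param config a config list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_config()), yaml::read_yaml(path))
  class(cfg) <- "synckit_config"
  cfg
}
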