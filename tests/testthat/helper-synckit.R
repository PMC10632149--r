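# Shared fixtures and independent oracles for the test suite.

# Homogeneous Poisson spike train on [0, duration].
poisson_train <- function(lambda, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unique(sort(stats::runif(stats::rpois(1, lambda * duration), 0, duration)))
}

# Brute-force 4-connected component labelling (BFS), oracle for the
# union-find implementation used by the cluster test.
bfs_component_sizes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- list(c(i, j)); seen[i, j] <- TRUE; size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# A small but complete synthetic session (fast to generate).
tiny_generator_config <- function(seed = 1, ...) {
  defaults <- list(
    duration = 160, seed = seed,
    regions = c(PVZ = 2L, SSp = 3L),
    laser_onsets = 70, laser_hz = 20, laser_duration = 30,
    eeg_rate = 250, ecg_rate = 500)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Fast encoder settings for unit tests.
tiny_encoder_spec <- function(...) {
  defaults <- list(hidden = 16, conv_channels = 8, kernel = 5, latent = 4,
                   lr = 5e-3, max_epochs = 30, patience = 5)
  do.call(encoder_spec, utils::modifyList(defaults, list(...)))
}
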