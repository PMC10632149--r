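# Internal helpers shared across stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

#' Centred moving-average smoothing
#'
#' Moving mean with a centred window; edges are averaged over the part of the
#' window that lies inside the trace, so no samples are lost and a constant
#' trace stays constant.
#'
#' @param x numeric vector.
#' @param n window length in samples (coerced to at least 1).
#' @return smoothed numeric vector, same length as `x`.
#' @keywords internal
moving_mean <- function(x, n) {
  n <- max(1L, as.integer(round(n)))
  if (n == 1L || length(x) < 2L) return(x)
  kern <- rep(1, n)
  num <- stats::filter(x, kern / n, sides = 2)
  den <- stats::filter(rep(1, length(x)), kern / n, sides = 2)
  out <- as.numeric(num) / as.numeric(den)
  # stats::filter leaves NAs where the window sticks out; patch edges
  bad <- is.na(out)
  if (any(bad)) {
    idx <- which(bad)
    half <- n %/% 2
    for (i in idx) {
      lo <- max(1L, i - half)
      hi <- min(length(x), i + half)
      out[i] <- mean(x[lo:hi])
    }
  }
  out
}

# Gaussian-kernel smoothing with edge renormalization (kernel mass inside the
# trace sums to 1 at every position). sigma in samples.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0 || length(x) < 2L) return(x)
  # cap the kernel at the series length (short recordings): the edge
  # renormalization keeps the truncated kernel a proper weighted mean
  half <- max(1L, min(as.integer(ceiling(4 * sigma)),
                      as.integer((length(x) - 1) %/% 2)))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  num <- as.numeric(stats::filter(x, kern, sides = 2))
  den <- as.numeric(stats::filter(rep(1, length(x)), kern, sides = 2))
  out <- num / den
  bad <- which(is.na(out))
  for (i in bad) {
    lo <- max(1L, i - half)
    hi <- min(length(x), i + half)
    w <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(x[lo:hi] * w) / sum(w)
  }
  out
}

# Half-open binning convention used everywhere: sample/event at time t falls
# in bin floor((t - t0)/dt) + 1, i.e. bins [t0 + (i-1)dt, t0 + i*dt).
bin_index <- function(t, t0, dt) floor((t - t0) / dt + 1e-9) + 1L

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_validation <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
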