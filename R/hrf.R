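#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma impulse response: a response gamma peaking around
#' 5-6 s minus a scaled undershoot gamma peaking around 16 s, normalized to a
#' unit peak. This is the kernel through which all neural amplitude series are
#' mapped to BOLD in both the simulator and the design-matrix builders.
#'
#' @param t time in seconds (vectorized, must be >= 0).
#' @param peak_delay,undershoot_delay shape parameters (seconds) of the
#'   response and undershoot gammas (rate 1/s).
#' @param undershoot_ratio amplitude ratio of undershoot to response.
#' @return response values, unit peak; `hrf(0)` is 0.
#' @export
hrf <- function(t, peak_delay = 6, undershoot_delay = 16, undershoot_ratio = 1/6) {
  stopifnot(all(t >= 0))
  f <- function(x) {
    stats::dgamma(x, shape = peak_delay, rate = 1) -
      undershoot_ratio * stats::dgamma(x, shape = undershoot_delay, rate = 1)
  }
  grid <- seq(0, 32, by = 0.01)
  f(t) / max(f(grid))
}

# HRF sampled on the TR grid and normalized to unit sum, so that convolving a
# sustained unit boxcar yields a unit plateau. Amplitudes are then in plateau
# (percent-signal-change) units; simulator and GLM share this kernel.
# Cached per (tr, duration): the unit-peak normalization scans a dense grid.
.hrf_cache <- new.env(parent = emptyenv())
hrf_kernel <- function(tr, duration = 32) {
  key <- paste(tr, duration, sep = "_")
  k <- .hrf_cache[[key]]
  if (is.null(k)) {
    k <- hrf(seq(0, duration, by = tr))
    k <- k / sum(k)
    .hrf_cache[[key]] <- k
  }
  k
}

# causal discrete convolution of x with the plateau-normalized HRF, truncated
# to length(x)
convolve_hrf <- function(x, tr, duration = 32) {
  k <- hrf_kernel(tr, duration)
  y <- stats::convolve(x, rev(k), type = "open")
  y[seq_along(x)]
}
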