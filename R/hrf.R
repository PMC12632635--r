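#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma impulse response: a positive gamma density with
#' delay 6 s minus an undershoot gamma with delay 16 s scaled by 1/6 (unit
#' dispersions), evaluated on a grid of spacing \code{dt} over
#' \code{duration} seconds and peak-normalized to 1.
#'
#' @param dt sample spacing in seconds (> 0).
#' @param duration kernel support in seconds (default 32).
#' @return numeric vector of kernel samples starting at t = 0.
#' @export
double_gamma_hrf <- function(dt, duration = 32) {
  stopifnot(dt > 0)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Accumulate boxcar events onto a microtime grid of n_micro samples spaced dt.
# `amplitudes` scales each event's boxcar.
boxcar_microtime <- function(onsets, durations, amplitudes, n_micro, dt) {
  x <- numeric(n_micro)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(ceiling((onsets[i] + durations[i]) / dt), n_micro)
    if (a <= b && a <= n_micro) x[a:b] <- x[a:b] + amplitudes[i]
  }
  x
}

# Convolve a microtime series with the HRF kernel (causal, "open" convolution
# truncated to the input length).
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  y <- stats::convolve(x, rev(kernel), type = "open")
  y[seq_len(n)]
}

# Downsample a microtime series at mid-TR of each scan. With dt = TR/oversample
# scan s is read at time (s - 0.5) * TR.
downsample_midtr <- function(x, n_scans, oversample) {
  idx <- round((seq_len(n_scans) - 0.5) * oversample)
  x[pmin(pmax(idx, 1L), length(x))]
}

# Build HRF-convolved scan-resolution regressors for one run from event
# onsets/durations/amplitudes. Returns a vector of length n_scans.
convolved_regressor <- function(onsets, durations, amplitudes, n_scans, TR,
                                oversample = 16) {
  dt <- TR / oversample
  n_micro <- n_scans * oversample
  x <- boxcar_microtime(onsets, durations, amplitudes, n_micro, dt)
  h <- double_gamma_hrf(dt)
  downsample_midtr(convolve_hrf(x, h), n_scans, oversample)
}

# Drift regressors for one run: cosines at `freqs` cycles per run, plus no
# intercept (intercepts handled separately).
drift_basis <- function(n_scans, freqs = c(0.5, 1, 2)) {
  t <- (seq_len(n_scans) - 0.5) / n_scans
  X <- vapply(freqs, function(f) cos(2 * pi * f * t), numeric(n_scans))
  colnames(X) <- paste0("drift", freqs)
  X
}
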