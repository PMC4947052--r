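# Threshold-based extracellular spike detection.
#
# The detector operates on the band-pass filtered signal x (0.3-8 kHz),
# estimates the noise level robustly as sigma = median(|x|)/0.6745 (the
# median of |N(0, sigma^2)| equals 0.6745 sigma, so this is an unbiased
# noise estimate insensitive to the spikes themselves) and records a
# spike at every local extremum whose magnitude exceeds T = N_S * sigma
# with N_S = 8 by default.

#' Spike-detection parameters
#'
#' @param band_low_hz,band_high_hz band-pass edges in Hz (defaults 300
#'   and 8000).
#' @param n_s spike-detection coefficient: the threshold is `n_s` times
#'   the robust noise SD (default 8).
#' @param order Butterworth band-pass filter order (number of poles,
#'   default 4, applied forward-backward for zero phase).
#' @param refractory_ms dead time after each detection (default 1 ms).
#' @param blanking_ms window from `t` to `t + blanking_ms` after each stimulus
#'   excluded from detection to suppress stimulation artifacts
#'   (default 2 ms; set 0 to disable).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(band_low_hz = 300, band_high_hz = 8000,
                             n_s = 8, order = 4L, refractory_ms = 1,
                             blanking_ms = 2) {
  if (!(band_low_hz > 0 && band_high_hz > band_low_hz))
    stop_param("band edges must satisfy 0 < low < high")
  if (n_s <= 0) stop_param("n_s must be positive")
  if (order < 2L || order %% 2L != 0L)
    stop_param("filter order must be a positive even number")
  check_nonneg(c(refractory_ms, blanking_ms), "refractory/blanking")
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 n_s = n_s, order = as.integer(order),
                 refractory_ms = refractory_ms, blanking_ms = blanking_ms),
            class = "detection_params")
}

# Polynomial coefficients (descending powers, leading 1) from roots.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

#' Butterworth band-pass filter design
#'
#' Digital Butterworth band-pass via the analog prototype, band
#' transformation and bilinear transform with frequency pre-warping.
#' `order` counts the poles of the resulting band-pass filter (so
#' `order = 4` uses a 2-pole low-pass prototype).
#'
#' @param order total band-pass order (even).
#' @param low_hz,high_hz band edges in Hz.
#' @param fs sampling rate in Hz; `high_hz` must be below `fs/2`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(order, low_hz, high_hz, fs) {
  if (high_hz >= fs / 2)
    stop_param("band edge ", high_hz, " Hz incompatible with sampling rate ",
               fs, " Hz")
  if (!(low_hz > 0 && high_hz > low_hz)) stop_param("invalid band edges")
  if (order %% 2L != 0L) stop_param("band-pass order must be even")
  n <- order %/% 2L
  # analog low-pass prototype poles on the unit circle, Re < 0
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # pre-warped edges and low-pass -> band-pass transform
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1; w0 <- sqrt(w1 * w2)
  disc <- sqrt((p * bw)^2 / 4 - w0^2 + 0i)
  pb <- c(p * bw / 2 + disc, p * bw / 2 - disc)
  zb <- rep(0 + 0i, n)          # n analog zeros at s = 0
  gain <- bw^n                  # band-pass gain for a unity prototype
  # bilinear transform s = 2 fs (z-1)/(z+1)
  zd <- (2 * fs + pb) / (2 * fs - pb)
  zz <- c((2 * fs + zb) / (2 * fs - zb), rep(-1 + 0i, n))
  gain_d <- gain * Re(prod(2 * fs - zb) / prod(2 * fs - pb))
  a <- Re(poly_from_roots(zd))
  b <- Re(poly_from_roots(zz)) * gain_d
  list(b = b, a = a)
}

# Steady-state initial filter state for a unit-amplitude input
# (lfilter_zi): makes filtfilt start-up transients vanish for constant
# extensions.
filter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  y_ss <- sum(b) / sum(a)
  rev(cumsum(rev(b[-1] - a[-1] * y_ss)))
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and backward, squaring its magnitude
#' response and cancelling its phase, so spike timing is preserved.
#' The signal is extended by odd reflection at both ends and the filter
#' state is initialized at steady state, suppressing edge transients.
#'
#' @param b,a filter coefficients, e.g. from [butter_bandpass()].
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_iir <- function(b, a, x) {
  stopifnot(a[1] != 0)
  b <- b / a[1]; a <- a / a[1]
  nfilt <- max(length(a), length(b))
  padlen <- 3L * nfilt
  n <- length(x)
  if (n <= padlen)
    stop_param("signal too short (", n, " samples) for padlen ", padlen)
  ext <- c(2 * x[1] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- filter_zi(b, a)
  y <- .cpp_iir_filter(b, a, ext, zi * ext[1])
  y <- rev(.cpp_iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Robust noise-level estimate of a filtered signal
#'
#' `sigma = median(|x|) / 0.6745`: for Gaussian noise the median of the
#' absolute signal equals 0.6745 sigma, and the median is nearly
#' unaffected by the sparse large-amplitude spikes riding on the noise.
#'
#' @param x filtered-signal samples (non-empty, finite).
#' @return noise SD estimate in the units of `x`.
#' @examples
#' estimate_noise_sigma(c(-0.6745, 0, 0.6745))  # exactly 1
#' @export
estimate_noise_sigma <- function(x) {
  if (!length(x)) stop_param("empty signal")
  if (any(!is.finite(x))) stop_param("non-finite samples in signal")
  stats::median(abs(x)) / 0.6745
}

# Local-extremum spike picking on one filtered channel.
pick_spikes <- function(xf, threshold, fs, refractory_ms, exclude_mask) {
  over <- abs(xf) > threshold
  if (!is.null(exclude_mask)) over <- over & !exclude_mask
  idx <- which(over)
  if (!length(idx)) return(numeric(0))
  run_id <- cumsum(c(1L, diff(idx) > 1L))
  peaks <- vapply(split(idx, run_id), function(ii)
    ii[which.max(abs(xf[ii]))], integer(1))
  peaks <- sort(unname(peaks))
  refr <- refractory_ms / 1000 * fs
  keep <- logical(length(peaks))
  last <- -Inf
  for (i in seq_along(peaks)) {
    if (peaks[i] - last > refr) { keep[i] <- TRUE; last <- peaks[i] }
  }
  (peaks[keep] - 1L) / fs
}

#' Detect spikes on raw multi-channel traces
#'
#' Per channel: band-pass filter (zero phase), estimate the noise level
#' with [estimate_noise_sigma()], and record a spike at each local
#' extremum of the filtered trace whose magnitude exceeds
#' `n_s * sigma`, both polarities, with at most one detection per
#' refractory window. Samples inside the post-stimulus blanking window
#' are excluded.
#'
#' @param raw a `raw_recording` (see [generate_raw_trace()]).
#' @param params a [detection_params()].
#' @param stims optional [stimulation_log()] used for artifact blanking.
#' @param geometry geometry attached to the returned spike set.
#' @return a [spike_train_set()] with spike times in seconds.
#' @export
detect_spikes <- function(raw, params = detection_params(), stims = NULL,
                          geometry = array_geometry()) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sampling_rate_hz
  flt <- butter_bandpass(params$order, params$band_low_hz,
                         params$band_high_hz, fs)
  n <- ncol(raw$data)
  mask <- NULL
  if (!is.null(stims) && params$blanking_ms > 0) {
    mask <- logical(n)
    w <- ceiling(params$blanking_ms / 1000 * fs)
    for (t in stims$time_s) {
      i0 <- max(1L, floor(t * fs) + 1L)
      i1 <- min(n, i0 + w - 1L)
      if (i0 <= n) mask[i0:i1] <- TRUE
    }
  }
  el <- integer(0); tt <- numeric(0)
  for (ci in seq_len(nrow(raw$data))) {
    xf <- filtfilt_iir(flt$b, flt$a, raw$data[ci, ])
    sigma <- estimate_noise_sigma(xf)
    st <- pick_spikes(xf, params$n_s * sigma, fs, params$refractory_ms, mask)
    el <- c(el, rep.int(raw$channel_ids[ci], length(st)))
    tt <- c(tt, st)
  }
  spike_train_set(el, tt, geometry, duration_s = raw$duration_s)
}
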