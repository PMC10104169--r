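# Shared signal-processing primitives: zero-phase Butterworth filtering,
# IIR notch, staged anti-aliased decimation, FFT analytic signal.

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass for ordinary bands.
#' Bands whose lower edge falls below 1 percent of the sampling rate switch
#' to a linear-phase windowed-sinc FIR with integer delay compensation: an
#' IIR biquad cascade is numerically unstable at such low normalized
#' frequencies, and FIR filtering is the convention for slow-band phase
#' extraction anyway. Zero phase matters for every phase-based statistic
#' downstream.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param band numeric length-2, band edges in Hz.
#' @param order filter order of the one-way IIR prototype (default 4).
#' @return filtered vector, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, band, order = 4) {
  nyq <- fs / 2
  if (band[1] <= 0 || band[2] >= nyq) {
    stop(sprintf("band (%g, %g) Hz outside (0, Nyquist = %g)",
                 band[1], band[2], nyq))
  }
  if (band[1] < fs / 100) {
    L <- min(2 * floor((length(x) - 1) / 2), 2 * round(1.5 * fs / band[1]))
    h <- signal::fir1(L, band / nyq, type = "pass")
    pad <- L / 2                        # integer group delay of even order
    y <- signal::fftfilt(h, c(x, numeric(L)))
    return(as.numeric(y[(pad + 1):(pad + length(x))]))
  }
  bf <- signal::butter(order, band / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase low-pass Butterworth filter
#' @inheritParams bandpass_filter
#' @param cutoff_hz cutoff frequency, Hz.
#' @return filtered vector.
#' @keywords internal
lowpass_filter <- function(x, fs, cutoff_hz, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Mains notch filter
#'
#' Second-order IIR notch (biquad) at `freq_hz` with quality factor `q`,
#' applied forward-backward so the stop-band attenuation is doubled and the
#' phase response is flat.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param freq_hz notch center (default 50, European mains).
#' @param q quality factor; bandwidth is `freq_hz / q` (default 30).
#' @return filtered vector.
#' @export
notch_filter <- function(x, fs, freq_hz = 50, q = 30) {
  w0 <- 2 * pi * freq_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  as.numeric(signal::filtfilt(b / a[1], a / a[1], x))
}

# Factor a decimation ratio into stages <= 10 for numerically safe IIR design.
decim_stages <- function(q) {
  stages <- integer()
  while (q > 10) {
    f <- max(Filter(function(d) q %% d == 0, 2:10))
    if (length(f) == 0L) break
    stages <- c(stages, f)
    q <- q / f
  }
  c(stages, q)
}

#' Anti-aliased decimation
#'
#' Zero-phase Butterworth low-pass at 0.8 x the target Nyquist followed by
#' subsampling, in stages of at most 10x for numerical stability. Non-integer
#' ratios fall back to low-pass plus linear-interpolation resampling, with a
#' warning.
#'
#' @param x numeric vector.
#' @param fs input sampling rate, Hz.
#' @param fs_out target sampling rate, Hz.
#' @return list with `x` (decimated signal) and `fs` (realized rate).
#' @export
decimate_signal <- function(x, fs, fs_out) {
  if (fs == fs_out) return(list(x = x, fs = fs))
  if (fs < fs_out) stop("cannot decimate upward")
  q <- fs / fs_out
  if (abs(q - round(q)) < 1e-9) {
    for (qi in decim_stages(round(q))) {
      x <- lowpass_filter(x, fs, 0.8 * (fs / qi) / 2, order = 4)
      x <- x[seq(1L, length(x), by = qi)]
      fs <- fs / qi
    }
    list(x = x, fs = fs)
  } else {
    warning(sprintf(
      "fs %g is not an integer multiple of %g Hz; resampling by interpolation",
      fs, fs_out))
    x <- lowpass_filter(x, fs, 0.8 * fs_out / 2, order = 4)
    t_old <- (seq_along(x) - 1) / fs
    t_new <- seq(0, max(t_old), by = 1 / fs_out)
    list(x = stats::approx(t_old, x, xout = t_new)$y, fs = fs_out)
  }
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' @param x real numeric vector.
#' @return complex vector `x + i * H(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited component
#'
#' Band-pass filters `x` (zero phase) and returns the angle of its analytic
#' signal; phase 0 is the oscillation peak.
#'
#' @inheritParams bandpass_filter
#' @return phase in radians, (-pi, pi].
#' @export
instantaneous_phase <- function(x, fs, band, order = 4) {
  Arg(analytic_signal(bandpass_filter(x, fs, band, order)))
}

#' Instantaneous amplitude envelope of a band-limited component
#'
#' @inheritParams bandpass_filter
#' @return non-negative envelope, same units as `x`.
#' @export
instantaneous_amplitude <- function(x, fs, band, order = 4) {
  Mod(analytic_signal(bandpass_filter(x, fs, band, order)))
}

#' Remove a linear trend
#' @param x numeric vector.
#' @return detrended vector (least-squares line removed).
#' @keywords internal
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2          # centered time, orthogonal to mean
  x - mean(x) - t * sum(t * x) / sum(t * t)
}
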