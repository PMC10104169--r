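# Theta-gamma phase-amplitude coupling: entropy-based modulation index,
# comodulograms over the standard phase x amplitude grid, region-of-interest
# quantification, local and inter-regional variants.

#' Entropy-based modulation index
#'
#' Band-passes both signals (zero phase), extracts the phase of the slow
#' signal and the amplitude envelope of the fast signal from their analytic
#' signals, bins the mean envelope by phase, normalizes the bin means to a
#' distribution P, and returns `MI = (log N - H(P)) / log N`, the normalized
#' Kullback-Leibler divergence of P from uniform. MI is 0 when the envelope
#' is independent of phase and 1 when it is concentrated in a single phase
#' bin.
#'
#' @param phase_signal,amp_signal numeric vectors, same sampling rate and
#'   length.
#' @param fs sampling rate, Hz.
#' @param phase_band,amp_band band edges, Hz.
#' @param n_bins number of phase bins (default 18, i.e. 20-degree bins).
#' @return modulation index in \[0, 1\].
#' @export
modulation_index <- function(phase_signal, amp_signal, fs,
                             phase_band, amp_band, n_bins = 18) {
  stopifnot(length(phase_signal) == length(amp_signal))
  phase <- instantaneous_phase(phase_signal, fs, phase_band)
  amp <- instantaneous_amplitude(amp_signal, fs, amp_band)
  mi_from_phase_amp(phase, amp, n_bins)
}

# Core MI computation on extracted phase/amplitude series.
mi_from_phase_amp <- function(phase, amp, n_bins = 18) {
  if (all(amp == 0)) stop("amplitude envelope is zero everywhere: MI undefined")
  bin <- pmin(floor((phase + pi) / (2 * pi / n_bins)) + 1L, n_bins)
  m <- vapply(seq_len(n_bins),
              function(b) if (any(bin == b)) mean(amp[bin == b]) else 0,
              numeric(1))
  p <- m / sum(m)
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  (log(n_bins) - h) / log(n_bins)
}

#' Phase-amplitude comodulogram
#'
#' Modulation index over a grid of phase frequencies (centers 2-15 Hz, 1 Hz
#' step, 4 Hz bandwidth) by amplitude frequencies (centers 10-250 Hz, 5 Hz
#' step, 10 Hz bandwidth). Lower band edges are clipped at 1 Hz, and
#' amplitude bands are restricted to the Nyquist range; the nominal
#' phase-grid origin of 0 Hz would give degenerate bands, so the effective
#' grid starts at 2 Hz. Filtered phase series and envelopes are computed once
#' per unique band.
#'
#' @param phase_lfp,amp_lfp `lfp_signal`s (or `recording`s) supplying the
#'   phase and the amplitude signal; pass the same object for local PAC. At
#'   least ~25 s of signal is recommended for stable estimates.
#' @param phase_channel,amp_channel channel indices.
#' @param phase_centers,amp_centers grid centers, Hz.
#' @param phase_bw,amp_bw full bandwidths, Hz.
#' @param n_bins phase bins for the MI.
#' @return object of class `comodulogram`: list with `phase_freqs`,
#'   `amp_freqs`, `mi` (phase x amplitude matrix), and source labels.
#' @export
comodulogram <- function(phase_lfp, amp_lfp = phase_lfp,
                         phase_channel = 1L, amp_channel = phase_channel,
                         phase_centers = seq(2, 15, by = 1),
                         amp_centers = seq(10, 250, by = 5),
                         phase_bw = 4, amp_bw = 10, n_bins = 18) {
  stopifnot(ncol(phase_lfp$signals) == ncol(amp_lfp$signals),
            phase_lfp$fs == amp_lfp$fs)
  fs <- phase_lfp$fs
  nyq <- fs / 2
  amp_centers <- amp_centers[amp_centers + amp_bw / 2 < nyq]
  xp <- phase_lfp$signals[phase_channel, ]
  xa <- amp_lfp$signals[amp_channel, ]
  phases <- lapply(phase_centers, function(c0) {
    instantaneous_phase(xp, fs, c(max(1, c0 - phase_bw / 2), c0 + phase_bw / 2))
  })
  amps <- lapply(amp_centers, function(c0) {
    instantaneous_amplitude(xa, fs, c(max(1, c0 - amp_bw / 2), c0 + amp_bw / 2))
  })
  mi <- matrix(0, length(phase_centers), length(amp_centers),
               dimnames = list(phase_centers, amp_centers))
  for (i in seq_along(phase_centers)) {
    for (j in seq_along(amp_centers)) {
      mi[i, j] <- mi_from_phase_amp(phases[[i]], amps[[j]], n_bins)
    }
  }
  structure(list(phase_freqs = phase_centers, amp_freqs = amp_centers,
                 mi = mi,
                 phase_source = phase_lfp$regions[phase_channel],
                 amp_source = amp_lfp$regions[amp_channel]),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  pk <- arrayInd(which.max(x$mi), dim(x$mi))
  cat(sprintf(
    "<comodulogram> %s phase x %s amplitude; peak MI %.4f at (%g Hz, %g Hz)\n",
    x$phase_source, x$amp_source, max(x$mi),
    x$phase_freqs[pk[1]], x$amp_freqs[pk[2]]))
  invisible(x)
}

#' @export
plot.comodulogram <- function(x, ...) {
  graphics::image(x$phase_freqs, x$amp_freqs, x$mi,
                  xlab = "Phase frequency (Hz)",
                  ylab = "Amplitude frequency (Hz)",
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}

#' Quantify a comodulogram region of interest
#'
#' Mean MI over grid points whose phase and amplitude centers fall in the
#' requested ranges (inclusive). The region is always an explicit argument:
#' theta-gamma coupling is typically read out at 6-10 Hz x 40-60 Hz or
#' 7-10 Hz x 60-80 Hz depending on the analysis.
#'
#' @param cm a `comodulogram`.
#' @param phase_range_hz,amp_range_hz numeric `c(low, high)` ranges.
#' @return mean modulation index over the region.
#' @export
pac_quantify <- function(cm, phase_range_hz, amp_range_hz) {
  pi_sel <- cm$phase_freqs >= phase_range_hz[1] &
    cm$phase_freqs <= phase_range_hz[2]
  ai_sel <- cm$amp_freqs >= amp_range_hz[1] & cm$amp_freqs <= amp_range_hz[2]
  if (!any(pi_sel) || !any(ai_sel)) {
    stop("quantification region does not intersect the comodulogram grid")
  }
  mean(cm$mi[pi_sel, ai_sel])
}

#' Inter-regional phase-amplitude coupling
#'
#' Comodulogram with the phase taken from one region and the amplitude from
#' the other, e.g. mPFC-phase to dHPC-amplitude coupling.
#'
#' @param lfp an `lfp_signal` containing both regions (or pass two objects
#'   via `amp_lfp`).
#' @param phase_region,amp_region region labels.
#' @param amp_lfp optional separate `lfp_signal` for the amplitude region.
#' @param ... forwarded to [comodulogram()].
#' @return a `comodulogram`.
#' @export
interregional_pac <- function(lfp, phase_region = "mPFC",
                              amp_region = "dHPC", amp_lfp = lfp, ...) {
  if (ncol(lfp$signals) != ncol(amp_lfp$signals)) {
    stop("phase and amplitude signals must be simultaneous and equal length")
  }
  pc <- which(lfp$regions == phase_region)[1]
  ac <- which(amp_lfp$regions == amp_region)[1]
  if (is.na(pc) || is.na(ac)) stop("region not found")
  comodulogram(lfp, amp_lfp, phase_channel = pc, amp_channel = ac, ...)
}
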