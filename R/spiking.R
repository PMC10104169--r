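# Spike-field coupling via pairwise phase consistency (PPC), an unbiased
# estimator of phase-locking strength: the average cosine of all pairwise
# differences between spike phases.

#' Phase of the band-limited LFP at each spike time
#'
#' Band-passes the LFP (zero phase), forms the analytic signal, linearly
#' interpolates its real and imaginary parts at the spike times, and returns
#' the interpolated angle.
#'
#' @param st a `spike_train`.
#' @param lfp an `lfp_signal` (or `recording`).
#' @param band analysis band, Hz (within Nyquist).
#' @param channel LFP channel supplying the field.
#' @param spike_channel spike-train channel.
#' @return numeric vector of phases in (-pi, pi\], one per spike.
#' @export
spike_phases <- function(st, lfp, band, channel = 1L, spike_channel = 1L) {
  fs <- lfp$fs
  if (band[2] >= fs / 2) stop("band outside the Nyquist range")
  times <- st$spike_times[[spike_channel]]
  dur <- duration_s(lfp)
  if (length(times) && (min(times) < 0 || max(times) > dur)) {
    stop("spikes outside the LFP time range")
  }
  z <- analytic_signal(bandpass_filter(lfp$signals[channel, ], fs, band))
  t_grid <- (seq_along(z) - 1) / fs
  re <- stats::approx(t_grid, Re(z), xout = times, rule = 2)$y
  im <- stats::approx(t_grid, Im(z), xout = times, rule = 2)$y
  atan2(im, re)
}

#' Pairwise phase consistency
#'
#' `PPC = 2 / (N (N - 1)) * sum_{i<j} cos(theta_i - theta_j)`, computed via
#' the algebraically identical form `((N R)^2 - N) / (N (N - 1))` with `R`
#' the resultant length. Unlike the squared resultant, its expectation is 0
#' for uniform phases at any `N`.
#'
#' @param phases numeric vector of phases, radians (>= 2 values).
#' @return PPC, in \[-1/(N-1), 1\].
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2L) stop("PPC requires at least 2 phases")
  s <- sum(exp(1i * phases))
  (Mod(s)^2 - n) / (n * (n - 1))
}

#' PPC over fixed-length epochs with a minimum spike count
#'
#' Tiles the analysis period into non-overlapping epochs (default 25 s),
#' computes the PPC of the spike phases within each epoch, and retains only
#' epochs with at least `min_spikes` spikes (default 250); sparser epochs are
#' reported with `ppc = NA`.
#'
#' @param st a `spike_train`.
#' @param lfp an `lfp_signal`.
#' @param band analysis band, Hz.
#' @param epoch_s epoch length, seconds.
#' @param min_spikes minimum spikes per epoch for a valid estimate.
#' @param epochs optional `epoch_set` to tile instead of the whole record.
#' @param channel,spike_channel channel indices.
#' @return data frame of class `ppc_result` with columns `epoch_start_s`,
#'   `epoch_end_s`, `n_spikes`, `ppc`.
#' @export
ppc_by_epochs <- function(st, lfp, band, epoch_s = 25, min_spikes = 250,
                          epochs = NULL, channel = 1L, spike_channel = 1L) {
  base <- if (is.null(epochs)) {
    epoch_set(0, duration_s(lfp), "all")
  } else epochs
  tiles <- tile_epochs(base, epoch_s)
  phases_all <- spike_phases(st, lfp, band, channel, spike_channel)
  times <- st$spike_times[[spike_channel]]
  out <- lapply(seq_len(nrow(tiles)), function(i) {
    sel <- times >= tiles$start_s[i] & times < tiles$end_s[i]
    n <- sum(sel)
    data.frame(epoch_start_s = tiles$start_s[i], epoch_end_s = tiles$end_s[i],
               n_spikes = n,
               ppc = if (n >= min_spikes) ppc(phases_all[sel]) else NA_real_)
  })
  res <- do.call(rbind, out)
  class(res) <- c("ppc_result", "data.frame")
  res
}
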