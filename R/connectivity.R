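# Directed connectivity via the phase slope index (PSI): the slope of the
# cross-spectral phase across frequency is positive when the first signal
# temporally leads the second. Significance is assessed against a shuffle
# surrogate (randomized channel pairings x time randomization) with a t-test
# of the epoch-level PSI values against the surrogate distribution.

# Hanning-windowed segment FFTs of one epoch: n_freq x n_segments matrix.
segment_ffts <- function(x, seg_len, overlap = 0.5) {
  hop <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  m <- vapply(starts, function(s) h * x[s:(s + seg_len - 1L)],
              numeric(seg_len))
  stats::mvfft(m)
}

# PSI of one epoch from the two segment-FFT matrices, over band bin indices.
psi_from_ffts <- function(fa, fb, bins) {
  saa <- rowMeans(Mod(fa)^2)[bins]
  sbb <- rowMeans(Mod(fb)^2)[bins]
  sab <- rowMeans(fa * Conj(fb))[bins]
  cc <- sab / sqrt(saa * sbb)
  nb <- length(cc)
  sum(Im(Conj(cc[-nb]) * cc[-1]))
}

band_bins <- function(fs, seg_len, band) {
  freqs <- (0:(floor(seg_len / 2))) * fs / seg_len
  bins <- which(freqs >= band[1] & freqs <= band[2])
  if (band[2] > fs / 2) stop("band exceeds the Nyquist frequency")
  if (length(bins) < 2L) {
    stop("fewer than 2 frequency bins in band: increase segleng_s or widen band")
  }
  bins
}

#' Phase slope index between two signals
#'
#' Cuts the data into epochs of `epleng_s` seconds and Hanning-windowed
#' segments of `segleng_s` seconds (50 percent overlap), averages the segment
#' cross-spectra within each epoch, and accumulates
#' `Im(Conj(C(f)) * C(f + df))` over the band, where `C` is the complex
#' coherency. Positive values mean the first signal leads. Data shorter than
#' one epoch are analyzed as a single full-length epoch, with a warning.
#'
#' @param x,y numeric vectors, simultaneous and equal length.
#' @param fs sampling rate, Hz.
#' @param band analysis band `c(low, high)`, Hz; must contain at least two
#'   frequency bins of width `1 / segleng_s`.
#' @param epleng_s epoch length, seconds (default 60).
#' @param segleng_s segment length, seconds (default 1).
#' @return object of class `psi_estimate`: `psi_epochs` (per-epoch PSI),
#'   `psi` (their mean), `jackknife_sd`, `psi_norm` (mean / jackknife SD),
#'   plus the analysis parameters.
#' @export
phase_slope_index <- function(x, y, fs, band, epleng_s = 60, segleng_s = 1) {
  stopifnot(length(x) == length(y))
  seg_len <- round(segleng_s * fs)
  bins <- band_bins(fs, seg_len, band)
  ep_len <- round(epleng_s * fs)
  n_ep <- floor(length(x) / ep_len)
  if (n_ep < 1L) {
    warning("data shorter than one epoch: using the full record as one epoch")
    ep_len <- length(x)
    n_ep <- 1L
  }
  psi_ep <- vapply(seq_len(n_ep), function(e) {
    idx <- ((e - 1L) * ep_len + 1L):(e * ep_len)
    psi_from_ffts(segment_ffts(x[idx], seg_len),
                  segment_ffts(y[idx], seg_len), bins)
  }, numeric(1))
  m <- mean(psi_ep)
  jk <- if (n_ep > 1L) stats::sd(psi_ep) / sqrt(n_ep) else NA_real_
  structure(list(psi_epochs = psi_ep, psi = m, jackknife_sd = jk,
                 psi_norm = if (is.na(jk) || jk == 0) NA_real_ else m / jk,
                 band = band, epleng_s = ep_len / fs,
                 segleng_s = segleng_s, n_epochs = n_ep, fs = fs),
            class = "psi_estimate")
}

#' @export
print.psi_estimate <- function(x, ...) {
  cat(sprintf("<psi_estimate> band %g-%g Hz: psi = %.4g over %d epoch(s)\n",
              x$band[1], x$band[2], x$psi, x$n_epochs))
  invisible(x)
}

#' Shuffle surrogate distribution for the PSI
#'
#' Destroys the temporal relationship between the regions while preserving
#' each signal's autostructure: on each draw a random channel pair is taken
#' (one channel per region, all combinations used over draws) and the second
#' region's signal is randomized, either by a random circular time shift
#' (default) or by permuting epoch order; the PSI of the randomized pair is
#' computed exactly as for the original data.
#'
#' @param sig_a,sig_b channels x samples matrices (or vectors) for the two
#'   regions.
#' @param fs sampling rate, Hz.
#' @param band analysis band, Hz.
#' @param n number of shuffles (default 1000; fewer than 100 gives an
#'   unstable null and warns).
#' @param seed integer seed for the shuffle randomness.
#' @param scheme `"circular_shift"` or `"epoch_permute"`.
#' @param epleng_s,segleng_s as in [phase_slope_index()].
#' @return numeric vector of `n` surrogate PSI values (epoch means).
#' @export
psi_surrogate <- function(sig_a, sig_b, fs, band, n = 1000, seed = 1L,
                          scheme = c("circular_shift", "epoch_permute"),
                          epleng_s = 60, segleng_s = 1) {
  scheme <- match.arg(scheme)
  if (n < 100) warning("fewer than 100 shuffles: surrogate null is unstable")
  if (is.vector(sig_a)) sig_a <- matrix(sig_a, 1)
  if (is.vector(sig_b)) sig_b <- matrix(sig_b, 1)
  set.seed(seed)
  seg_len <- round(segleng_s * fs)
  bins <- band_bins(fs, seg_len, band)
  ns <- ncol(sig_a)
  ep_len <- round(epleng_s * fs)
  n_ep <- max(1L, floor(ns / ep_len))
  if (floor(ns / ep_len) < 1L) ep_len <- ns
  # cache region-a segment FFTs (a is never randomized)
  fft_a <- lapply(seq_len(nrow(sig_a)), function(ch) {
    lapply(seq_len(n_ep), function(e) {
      idx <- ((e - 1L) * ep_len + 1L):(e * ep_len)
      segment_ffts(sig_a[ch, idx], seg_len)
    })
  })
  vapply(seq_len(n), function(s) {
    ca <- sample.int(nrow(sig_a), 1L)
    cb <- sample.int(nrow(sig_b), 1L)
    b <- sig_b[cb, seq_len(ep_len * n_ep)]
    if (scheme == "circular_shift") {
      shift <- sample.int(length(b) - 1L, 1L)
      b <- c(b[(shift + 1L):length(b)], b[seq_len(shift)])
      ep_order <- seq_len(n_ep)
    } else {
      ep_order <- if (n_ep > 1L) sample.int(n_ep) else 1L
    }
    mean(vapply(seq_len(n_ep), function(e) {
      idx <- ((ep_order[e] - 1L) * ep_len + 1L):(ep_order[e] * ep_len)
      psi_from_ffts(fft_a[[ca]][[e]], segment_ffts(b[idx], seg_len), bins)
    }, numeric(1)))
  }, numeric(1))
}

#' Significance of the PSI against its shuffle
#'
#' Two-sample two-sided t-test of the epoch-level PSI values against the
#' surrogate distribution. Degenerate (zero-variance) inputs take an
#' exact-equality fast path.
#'
#' @param psi_epochs numeric vector of epoch-level PSI values (>= 2).
#' @param surrogate numeric vector of surrogate PSI values.
#' @return two-sided p-value.
#' @export
psi_significance <- function(psi_epochs, surrogate) {
  if (length(psi_epochs) < 2L) stop("need at least 2 epoch-level PSI values")
  if (stats::sd(psi_epochs) == 0 && stats::sd(surrogate) == 0) {
    return(if (isTRUE(all.equal(mean(psi_epochs), mean(surrogate)))) 1 else 0)
  }
  stats::t.test(psi_epochs, surrogate)$p.value
}

#' Full PSI analysis with surrogate correction
#'
#' Computes the raw PSI between the two regions of an LFP, the shuffle
#' surrogate distribution, the surrogate-corrected PSI (raw minus surrogate
#' mean, removing chance effects), and its significance.
#'
#' @param lfp an `lfp_signal` containing both regions.
#' @param band analysis band, Hz (e.g. the theta or high-gamma band of
#'   [band_scheme()]).
#' @param region_a,region_b region labels; positive PSI means `region_a`
#'   leads.
#' @param epochs optional `epoch_set`; if given, the per-channel signals are
#'   the concatenated epoch segments and `epleng_s` defaults to the full
#'   concatenated length (the behavioral-visit convention). Otherwise the
#'   continuous signal is used with `epleng_s = 60`.
#' @param epleng_s,segleng_s epoch/segment lengths, seconds.
#' @param n_shuffles surrogate draws (default 1000).
#' @param seed seed for the surrogate randomness.
#' @param scheme surrogate scheme, see [psi_surrogate()].
#' @return object of class `psi_result`: band, `psi_raw`, `surrogate_mean`,
#'   `surrogate_sd`, `psi_corrected`, `p_value`, `n_shuffles`, and the
#'   underlying `psi_estimate`.
#' @export
psi_analysis <- function(lfp, band, region_a = "mPFC", region_b = "dHPC",
                         epochs = NULL, epleng_s = NULL, segleng_s = 1,
                         n_shuffles = 1000, seed = 1L,
                         scheme = "circular_shift") {
  sa <- region_channels(lfp, region_a)
  sb <- region_channels(lfp, region_b)
  if (!is.null(epochs)) {
    cat_rows <- function(m) {
      do.call(cbind, lapply(epoch_segments_matrix(m, lfp$fs, epochs), identity))
    }
    sa <- cat_rows(sa)
    sb <- cat_rows(sb)
    if (is.null(epleng_s)) epleng_s <- ncol(sa) / lfp$fs
  }
  if (is.null(epleng_s)) epleng_s <- 60
  est <- phase_slope_index(sa[1, ], sb[1, ], lfp$fs, band,
                           epleng_s = epleng_s, segleng_s = segleng_s)
  surr <- psi_surrogate(sa, sb, lfp$fs, band, n = n_shuffles, seed = seed,
                        scheme = scheme, epleng_s = epleng_s,
                        segleng_s = segleng_s)
  p <- if (est$n_epochs >= 2L) psi_significance(est$psi_epochs, surr) else {
    # single-epoch fallback: position of the raw PSI in the surrogate null
    2 * min(mean(surr >= est$psi), mean(surr <= est$psi))
  }
  structure(list(band = band, region_a = region_a, region_b = region_b,
                 psi_raw = est$psi, surrogate_mean = mean(surr),
                 surrogate_sd = stats::sd(surr),
                 psi_corrected = est$psi - mean(surr),
                 p_value = p, n_shuffles = n_shuffles,
                 estimate = est, surrogate = surr, scheme = scheme),
            class = "psi_result")
}

# epoch_segments for a channels x samples matrix: list of sub-matrices.
epoch_segments_matrix <- function(m, fs, epochs) {
  lapply(seq_len(nrow(epochs)), function(i) {
    i0 <- floor(epochs$start_s[i] * fs) + 1L
    i1 <- min(floor(epochs$end_s[i] * fs), ncol(m))
    m[, i0:i1, drop = FALSE]
  })
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf(
    "<psi_result> %s->%s, band %g-%g Hz\n  raw %.4g, corrected %.4g (surrogate %.4g +/- %.4g), p = %.3g (%d shuffles)\n",
    x$region_a, x$region_b, x$band[1], x$band[2], x$psi_raw,
    x$psi_corrected, x$surrogate_mean, x$surrogate_sd, x$p_value,
    x$n_shuffles))
  invisible(x)
}
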