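# Raw-recording preprocessing: LFP extraction (detrend, notch, decimate),
# MUA threshold-crossing extraction, accelerometer rest detection, firing-rate
# binning.

#' Extract local field potentials
#'
#' Per channel: linear detrend, mains notch (zero-phase biquad), anti-aliased
#' decimation to `lfp_fs` Hz.
#'
#' @param rec a `recording` with `fs >= 1000`.
#' @param notch_hz mains frequency to notch, Hz (default 50); `NA` skips the
#'   notch.
#' @param lfp_fs target LFP sampling rate, Hz (default 1000).
#' @param notch_q notch quality factor (default 30).
#' @return an `lfp_signal` at `lfp_fs` Hz with the applied settings in
#'   `provenance`.
#' @export
extract_lfp <- function(rec, notch_hz = 50, lfp_fs = 1000, notch_q = 30) {
  stopifnot(rec$fs >= 1000)
  out <- NULL
  fs_out <- lfp_fs
  for (i in seq_len(nrow(rec$signals))) {
    x <- detrend_linear(rec$signals[i, ])
    if (!is.na(notch_hz)) x <- notch_filter(x, rec$fs, notch_hz, notch_q)
    d <- decimate_signal(x, rec$fs, lfp_fs)
    fs_out <- d$fs
    if (is.null(out)) {
      out <- matrix(0, nrow(rec$signals), length(d$x))
      rownames(out) <- rownames(rec$signals)
    }
    out[i, ] <- d$x
  }
  lfp_signal(out, fs_out, rec$regions,
             provenance = list(detrend = "linear", notch_hz = notch_hz,
                               notch_q = notch_q, source_fs = rec$fs,
                               decimated_to = fs_out))
}

#' Extract multi-unit activity by threshold crossing
#'
#' Subtracts a nearby reference channel (cancelling movement artifacts common
#' to both), band-passes 450-6000 Hz (zero phase), estimates sigma robustly as
#' `median(|x|) / 0.6745`, and takes negative threshold crossings at
#' `-threshold_sigma * sigma` with a refractory lockout so one waveform is not
#' counted twice.
#'
#' @param rec a `recording` with `fs >= 12000` (Nyquist for the 6 kHz band
#'   edge).
#' @param channel target channel index.
#' @param reference_channel reference channel index (must differ from
#'   `channel`); `NA` skips subtraction.
#' @param band MUA band, Hz.
#' @param threshold_sigma sigma multiplier (default 3).
#' @param lockout_s refractory lockout, seconds (default 1 ms).
#' @return a `spike_train` with one channel.
#' @export
extract_mua <- function(rec, channel = 1L, reference_channel = NA,
                        band = c(450, 6000), threshold_sigma = 3,
                        lockout_s = 0.001) {
  stopifnot(rec$fs >= 2 * band[2])
  if (!is.na(reference_channel) && reference_channel == channel) {
    stop("reference channel must differ from the target channel")
  }
  x <- rec$signals[channel, ]
  if (!is.na(reference_channel)) x <- x - rec$signals[reference_channel, ]
  xf <- bandpass_filter(x, rec$fs, band)
  sigma <- stats::median(abs(xf)) / 0.6745
  thr <- -threshold_sigma * sigma
  below <- xf < thr
  crossings <- which(below & !c(FALSE, below[-length(below)]))
  if (length(crossings)) {
    lock <- round(lockout_s * rec$fs)
    keep <- logical(length(crossings))
    last <- -Inf
    for (i in seq_along(crossings)) {
      if (crossings[i] - last > lock) {
        keep[i] <- TRUE
        last <- crossings[i]
      }
    }
    crossings <- crossings[keep]
  }
  spike_train(list((crossings - 1) / rec$fs),
              threshold_sigma = threshold_sigma,
              duration_s = duration_s(rec))
}

#' Detect rest epochs from the accelerometer
#'
#' Computes the instantaneous acceleration module `sqrt(x^2 + y^2 + z^2)`, its
#' variance in sliding windows (default 0.5 s, 50 percent overlap), and
#' returns contiguous sub-threshold runs of 2-10 s as rest epochs. Runs longer
#' than `max_s` are split into segments of at most `max_s`. The threshold
#' defaults to a percentile of the session's windowed variance because mice
#' rest only a fraction of the time.
#'
#' @param rec a `recording` with an accelerometer.
#' @param window_s sliding variance window, seconds.
#' @param overlap fractional window overlap.
#' @param threshold absolute ACC-variance threshold; if `NULL`, taken as the
#'   `threshold_percentile` quantile of the session.
#' @param threshold_percentile percentile (0-100) defining the threshold when
#'   `threshold` is `NULL`.
#' @param min_s,max_s rest-duration bounds, seconds (default 2 and 10).
#' @param exclude_events drop rest time overlapping event-marked intervals
#'   (object visits, tones) so "rest" never doubles as task time.
#' @return an `epoch_set` labeled `"rest"`.
#' @export
detect_rest_epochs <- function(rec, window_s = 0.5, overlap = 0.5,
                               threshold = NULL, threshold_percentile = 20,
                               min_s = 2, max_s = 10,
                               exclude_events = TRUE) {
  if (is.null(rec$accel)) stop("recording has no accelerometer")
  fs <- rec$fs
  mod <- sqrt(colSums(rec$accel^2))
  if (all(mod == 0)) {
    warning("all-zero accelerometer: everything classified as rest")
  }
  win <- max(2L, round(window_s * fs))
  hop <- max(1L, round(win * (1 - overlap)))
  starts <- seq(1L, length(mod) - win + 1L, by = hop)
  acc_var <- vapply(starts, function(s) stats::var(mod[s:(s + win - 1L)]),
                    numeric(1))
  if (is.null(threshold)) {
    threshold <- stats::quantile(acc_var, threshold_percentile / 100,
                                 names = FALSE)
  }
  quiet <- acc_var <= threshold
  if (all(mod == 0)) quiet[] <- TRUE
  # merge consecutive quiet windows into intervals
  r <- rle(quiet)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  ivals <- NULL
  for (k in which(r$values)) {
    t0 <- (starts[starts_idx[k]] - 1L) / fs
    t1 <- (starts[ends_idx[k]] - 1L + win) / fs
    ivals <- rbind(ivals, c(t0, min(t1, length(mod) / fs)))
  }
  if (is.null(ivals)) return(epoch_set())
  if (exclude_events && !is.null(rec$events) && nrow(rec$events) > 0L) {
    ivals <- subtract_intervals(ivals, cbind(rec$events$onset_s,
                                             rec$events$offset_s))
  }
  if (is.null(ivals) || nrow(ivals) == 0L) return(epoch_set())
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_len(nrow(ivals))) {
    len <- ivals[i, 2] - ivals[i, 1]
    if (len < min_s) next
    n_seg <- ceiling(len / max_s)
    bounds <- seq(ivals[i, 1], ivals[i, 2], length.out = n_seg + 1L)
    for (j in seq_len(n_seg)) {
      if (bounds[j + 1] - bounds[j] >= min_s) {
        out_s <- c(out_s, bounds[j]); out_e <- c(out_e, bounds[j + 1])
      }
    }
  }
  if (!length(out_s)) return(epoch_set())
  epoch_set(out_s, out_e, "rest")
}

# Set difference of interval unions: rows of `a` minus rows of `b`.
subtract_intervals <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    pieces <- matrix(a[i, ], ncol = 2)
    for (j in seq_len(nrow(b))) {
      nxt <- NULL
      for (k in seq_len(nrow(pieces))) {
        s <- pieces[k, 1]; e <- pieces[k, 2]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be <= s || bs >= e) {
          nxt <- rbind(nxt, c(s, e))
        } else {
          if (bs > s) nxt <- rbind(nxt, c(s, bs))
          if (be < e) nxt <- rbind(nxt, c(be, e))
        }
      }
      pieces <- if (is.null(nxt)) matrix(numeric(), ncol = 2) else nxt
      if (nrow(pieces) == 0L) break
    }
    out <- rbind(out, pieces)
  }
  out
}

#' Bin spike counts into a firing-rate series
#'
#' Counts per non-overlapping window divided by the window length. The 3-s
#' window is used for quiet-alertness firing rates, the 10-ms window for
#' peri-stimulus rates around auditory events.
#'
#' @param st a `spike_train`.
#' @param window_s window length, seconds (> 0).
#' @param channel channel index.
#' @param duration_s series length, seconds; defaults to the train's duration.
#' @return numeric vector of rates (Hz), one per window, with window start
#'   times as the `time_s` attribute.
#' @export
bin_firing_rate <- function(st, window_s, channel = 1L,
                            duration_s = st$duration_s) {
  stopifnot(window_s > 0)
  if (is.na(duration_s)) {
    times <- st$spike_times[[channel]]
    duration_s <- if (length(times)) max(times) else window_s
  }
  n_win <- max(1L, floor(duration_s / window_s))
  times <- st$spike_times[[channel]]
  idx <- floor(times / window_s) + 1L        # half-open [k*w, (k+1)*w)
  counts <- tabulate(idx[idx >= 1L & idx <= n_win], nbins = n_win)
  rate <- counts / window_s
  attr(rate, "time_s") <- (seq_len(n_win) - 1L) * window_s
  rate
}
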