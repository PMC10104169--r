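#' Continuous multichannel recording
#'
#' Container for a raw or preprocessed extracellular recording: a channels x
#' samples signal matrix in microvolts, a sampling rate, a channel-to-region
#' map, an optional 3-axis accelerometer trace and an optional event table.
#'
#' @param signals numeric matrix, channels x samples, in microvolts. A vector
#'   is treated as a single channel.
#' @param fs sampling rate in Hz.
#' @param regions character vector, one region label per channel (e.g.
#'   `"mPFC"`, `"dHPC"`). Recycled if length 1.
#' @param accel optional 3 x samples matrix of accelerometer traces in g.
#' @param events optional data frame with columns `onset_s`, `offset_s`,
#'   `label`.
#' @param meta optional named list of provenance metadata.
#'
#' @return An object of class `recording`.
#' @export
recording <- function(signals, fs, regions, accel = NULL, events = NULL,
                      meta = list()) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  stopifnot(is.matrix(signals), is.numeric(signals), fs > 0)
  n_ch <- nrow(signals)
  if (length(regions) == 1L) regions <- rep(regions, n_ch)
  if (length(regions) != n_ch) {
    stop("`regions` must supply one label per channel")
  }
  if (is.null(rownames(signals))) {
    rownames(signals) <- paste0("ch", seq_len(n_ch))
  }
  dur <- ncol(signals) / fs
  if (!is.null(accel)) {
    stopifnot(is.matrix(accel), nrow(accel) == 3L)
  }
  if (!is.null(events) && nrow(events) > 0L) {
    stopifnot(all(c("onset_s", "offset_s", "label") %in% names(events)))
    if (any(events$onset_s < 0) || any(events$offset_s > dur + 1e-9)) {
      stop("event times fall outside the recording")
    }
  }
  structure(
    list(signals = signals, fs = fs, regions = regions, accel = accel,
         events = events, meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %.1f s at %g Hz\n",
              nrow(x$signals), ncol(x$signals) / x$fs, x$fs))
  cat("  regions:", paste(unique(x$regions), collapse = ", "), "\n")
  if (!is.null(x$accel)) cat("  accelerometer: 3 axes\n")
  if (!is.null(x$events)) cat(sprintf("  events: %d\n", nrow(x$events)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `recording` or `lfp_signal`.
#' @return length in seconds.
#' @export
duration_s <- function(rec) ncol(rec$signals) / rec$fs

#' Extract channels belonging to one region
#'
#' @param rec a `recording` or `lfp_signal`.
#' @param region region label to select.
#' @return matrix of the selected channels (channels x samples).
#' @export
region_channels <- function(rec, region) {
  sel <- rec$regions == region
  if (!any(sel)) stop(sprintf("no channel in region '%s'", region))
  rec$signals[sel, , drop = FALSE]
}

#' Labeled half-open time intervals
#'
#' An `epoch_set` is a data frame of half-open intervals `[start_s, end_s)`
#' with a label per interval, the common currency between rest detection,
#' behavioral visit epochs and trial epochs.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param label character vector of labels (recycled).
#' @return data frame of class `epoch_set` with columns `start_s`, `end_s`,
#'   `label`.
#' @export
epoch_set <- function(start_s = numeric(), end_s = numeric(),
                      label = character()) {
  if (length(label) == 1L) label <- rep(label, length(start_s))
  stopifnot(length(start_s) == length(end_s),
            length(label) == length(start_s))
  if (any(end_s <= start_s)) stop("epoch_set requires start < end")
  if (length(label) && any(!nzchar(label))) stop("labels must be non-empty")
  structure(
    data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
               label = as.character(label), stringsAsFactors = FALSE),
    class = c("epoch_set", "data.frame")
  )
}

#' Tile epochs into fixed-length non-overlapping analysis windows
#'
#' Splits each epoch into consecutive windows of `window_s` seconds,
#' discarding the ragged tail. Used to turn 2-10 s rest periods into the 3-s
#' quiet-alertness windows the spectral analyses consume.
#'
#' @param epochs an `epoch_set`.
#' @param window_s window length in seconds.
#' @return an `epoch_set` of tiled windows (labels inherited).
#' @export
tile_epochs <- function(epochs, window_s = 3) {
  stopifnot(window_s > 0)
  starts <- numeric(); ends <- numeric(); labs <- character()
  for (i in seq_len(nrow(epochs))) {
    n_win <- floor((epochs$end_s[i] - epochs$start_s[i]) / window_s)
    if (n_win < 1L) next
    s <- epochs$start_s[i] + (seq_len(n_win) - 1L) * window_s
    starts <- c(starts, s)
    ends <- c(ends, s + window_s)
    labs <- c(labs, rep(epochs$label[i], n_win))
  }
  epoch_set(starts, ends, labs)
}

#' Cut a signal vector into epoch segments
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param epochs an `epoch_set`.
#' @return list of numeric vectors, one per epoch.
#' @keywords internal
epoch_segments <- function(x, fs, epochs) {
  lapply(seq_len(nrow(epochs)), function(i) {
    i0 <- floor(epochs$start_s[i] * fs) + 1L
    i1 <- floor(epochs$end_s[i] * fs)
    x[i0:min(i1, length(x))]
  })
}

#' Preprocessed local field potential
#'
#' @param signals channels x samples matrix, microvolts.
#' @param fs sampling rate in Hz (nominally 1000 after decimation).
#' @param regions channel-to-region map.
#' @param provenance named list of the filter/decimation settings applied.
#' @return object of class `lfp_signal`.
#' @export
lfp_signal <- function(signals, fs, regions, provenance = list()) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1L)
  if (anyNA(signals)) stop("LFP must not contain NaN")
  obj <- recording(signals, fs, regions, meta = list())
  obj$provenance <- provenance
  class(obj) <- c("lfp_signal", "recording")
  obj
}

#' Multi-unit spike trains
#'
#' @param spike_times list of numeric vectors (seconds), one per channel;
#'   strictly increasing within a channel.
#' @param threshold_sigma the sigma multiplier used at detection.
#' @param duration_s recording duration the trains live in.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(spike_times, threshold_sigma = NA_real_,
                        duration_s = NA_real_) {
  if (is.numeric(spike_times)) spike_times <- list(spike_times)
  for (st in spike_times) {
    if (length(st) > 1L && any(diff(st) <= 0)) {
      stop("spike times must be strictly increasing per channel")
    }
    if (!is.na(duration_s) && length(st) &&
        (min(st) < 0 || max(st) > duration_s)) {
      stop("spike times outside recording duration")
    }
  }
  structure(list(spike_times = spike_times,
                 threshold_sigma = threshold_sigma,
                 duration_s = duration_s),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- vapply(x$spike_times, length, integer(1))
  cat(sprintf("<spike_train> %d channel(s), %s spikes\n",
              length(n), paste(n, collapse = "/")))
  invisible(x)
}
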