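# Auditory evoked potentials (AEP) and oddball mismatch negativity (MMN) in
# the mPFC: trial epoching with baseline correction, per-trial response
# detection and response ratio, P2/P3 component quantification (amplitude
# and associated multi-unit firing), and flip-flop difference-wave analysis.

#' Epoch an LFP around stimulus events
#'
#' Cuts one snippet per event from `-pre_ms` to `+post_ms` around the onset
#' and subtracts each trial's mean pre-stimulus baseline. Trials extending
#' past the recording are dropped with a warning.
#'
#' @param lfp an `lfp_signal` (or `recording`).
#' @param events data frame with an `onset_s` column (one row per trial).
#' @param pre_ms,post_ms window bounds, milliseconds.
#' @param channel channel index.
#' @return object of class `trial_matrix`: trials x time matrix (microvolts,
#'   baseline-corrected) with `time_ms` attribute (0 = stimulus onset) and
#'   the retained event rows as the `events` attribute.
#' @export
epoch_trials <- function(lfp, events, pre_ms = 500, post_ms = 500,
                         channel = 1L) {
  fs <- lfp$fs
  x <- lfp$signals[channel, ]
  n_pre <- round(pre_ms / 1000 * fs)
  n_post <- round(post_ms / 1000 * fs)
  on_idx <- round(events$onset_s * fs) + 1L
  ok <- on_idx - n_pre >= 1L & on_idx + n_post <= length(x)
  if (any(!ok)) {
    warning(sprintf("%d trial(s) extend past the recording and were dropped",
                    sum(!ok)))
  }
  on_idx <- on_idx[ok]
  m <- t(vapply(on_idx, function(i0) x[(i0 - n_pre):(i0 + n_post)],
                numeric(n_pre + n_post + 1L)))
  base <- rowMeans(m[, seq_len(n_pre), drop = FALSE])
  m <- m - base
  structure(m, time_ms = ((-n_pre):n_post) / fs * 1000,
            events = events[ok, , drop = FALSE], fs = fs,
            class = c("trial_matrix", "matrix"))
}

#' Detect per-trial auditory evoked responses
#'
#' A trial is responsive when its peak absolute amplitude inside the
#' detection window exceeds `k` times the SD of its own pre-stimulus
#' baseline. The response ratio is the number of responsive trials over the
#' number of trials.
#'
#' @param trials a `trial_matrix`.
#' @param window_ms detection window, milliseconds post-stimulus (default
#'   10-350 ms, bracketing the P2 and P3 components).
#' @param k baseline-SD multiplier (default 3).
#' @return list with `responsive` (logical per trial) and `response_ratio`.
#' @export
detect_aep <- function(trials, window_ms = c(10, 350), k = 3) {
  t_ms <- attr(trials, "time_ms")
  if (nrow(trials) < 1L) stop("need at least one trial")
  base_sd <- apply(trials[, t_ms < 0, drop = FALSE], 1, stats::sd)
  if (any(base_sd == 0)) stop("zero-variance pre-stimulus baseline")
  win <- t_ms >= window_ms[1] & t_ms < window_ms[2]
  peak <- apply(abs(trials[, win, drop = FALSE]), 1, max)
  resp <- peak > k * base_sd
  list(responsive = resp, response_ratio = mean(resp))
}

# Component windows (ms post-stimulus): P2 and P3, half-open.
component_window <- function(component = c("P2", "P3")) {
  switch(match.arg(component), P2 = c(40, 70), P3 = c(200, 300))
}

#' Component amplitude and associated firing rate
#'
#' Amplitude: peak of the trial-averaged (baseline-corrected) waveform
#' within the component window. Firing rate: mean multi-unit rate in 10-ms
#' bins within the window, averaged across trials.
#'
#' @param trials a `trial_matrix`.
#' @param component `"P2"` (40-70 ms) or `"P3"` (200-300 ms).
#' @param spikes optional `spike_train` recorded simultaneously.
#' @param spike_channel spike-train channel.
#' @param bin_ms firing-rate bin, milliseconds.
#' @return list with `amplitude` (microvolts) and `firing_rate` (Hz; 0 when
#'   no spikes are supplied or none fall in the window).
#' @export
component_metrics <- function(trials, component = c("P2", "P3"),
                              spikes = NULL, spike_channel = 1L,
                              bin_ms = 10) {
  win <- component_window(component)
  t_ms <- attr(trials, "time_ms")
  erp <- colMeans(trials)
  sel <- t_ms >= win[1] & t_ms < win[2]
  amplitude <- max(erp[sel])
  firing_rate <- 0
  if (!is.null(spikes)) {
    onsets <- attr(trials, "events")$onset_s
    times <- spikes$spike_times[[spike_channel]]
    w_s <- win / 1000
    n_bins <- floor((w_s[2] - w_s[1]) / (bin_ms / 1000))
    count <- 0
    for (on in onsets) {
      count <- count + sum(times >= on + w_s[1] &
                             times < on + w_s[1] + n_bins * bin_ms / 1000)
    }
    firing_rate <- count / (length(onsets) * n_bins * bin_ms / 1000)
  }
  list(amplitude = amplitude, firing_rate = firing_rate,
       window_ms = win, component = match.arg(component))
}

#' Oddball mismatch-negativity analysis
#'
#' Flip-flop oddball: each physical tone frequency serves as deviant in one
#' block and as standard in the other. For each frequency the deviant trials
#' (from its deviant block) are averaged and compared with the standard
#' trials *of the same frequency* from the other block — never across
#' frequencies — yielding a difference wave (deviant minus standard) and its
#' area under the curve over the MMN window.
#'
#' @param lfp an `lfp_signal` (or `recording`).
#' @param oddball_events data frame with `onset_s`, `freq_hz`, `role`
#'   (`"standard"`/`"deviant"`) and `block` columns.
#' @param pre_ms,post_ms epoching window, milliseconds.
#' @param mmn_window_ms integration window for the AUC, milliseconds
#'   post-stimulus (default 40-200).
#' @param channel channel index.
#' @return object of class `mmn_result`: per-frequency list with
#'   `standard_erp`, `deviant_erp`, `difference_wave` (microvolts),
#'   `auc` (microvolt-milliseconds over the MMN window) and trial counts;
#'   plus `time_ms` and the window used.
#' @export
mmn_analysis <- function(lfp, oddball_events, pre_ms = 100, post_ms = 400,
                         mmn_window_ms = c(40, 200), channel = 1L) {
  stopifnot(all(c("onset_s", "freq_hz", "role", "block") %in%
                  names(oddball_events)))
  trials <- epoch_trials(lfp, oddball_events, pre_ms, post_ms, channel)
  ev <- attr(trials, "events")
  t_ms <- attr(trials, "time_ms")
  combos <- list()
  for (f in sort(unique(ev$freq_hz))) {
    dev_sel <- ev$freq_hz == f & ev$role == "deviant"
    std_sel <- ev$freq_hz == f & ev$role == "standard"
    if (!any(dev_sel) || !any(std_sel)) {
      warning(sprintf(
        "frequency %g Hz missing a deviant or standard block: partial result", f))
      next
    }
    dev_blocks <- unique(ev$block[dev_sel])
    std_blocks <- unique(ev$block[std_sel])
    if (length(intersect(dev_blocks, std_blocks))) {
      warning(sprintf(
        "frequency %g Hz is deviant and standard within one block", f))
    }
    dev_erp <- colMeans(trials[dev_sel, , drop = FALSE])
    std_erp <- colMeans(trials[std_sel, , drop = FALSE])
    diff_wave <- dev_erp - std_erp
    win <- t_ms >= mmn_window_ms[1] & t_ms <= mmn_window_ms[2]
    auc <- sum(diff(t_ms[win]) *
                 (diff_wave[win][-1] + diff_wave[win][-sum(win)]) / 2)
    combos[[sprintf("%gkHz_deviant", f / 1000)]] <- list(
      freq_hz = f, standard_erp = std_erp, deviant_erp = dev_erp,
      difference_wave = diff_wave, auc = auc,
      n_deviant = sum(dev_sel), n_standard = sum(std_sel))
  }
  structure(list(combinations = combos, time_ms = t_ms,
                 mmn_window_ms = mmn_window_ms),
            class = "mmn_result")
}

#' @export
print.mmn_result <- function(x, ...) {
  cat(sprintf("<mmn_result> window %g-%g ms\n",
              x$mmn_window_ms[1], x$mmn_window_ms[2]))
  for (nm in names(x$combinations)) {
    cb <- x$combinations[[nm]]
    cat(sprintf("  %s: AUC = %.1f uV*ms (%d deviant / %d standard trials)\n",
                nm, cb$auc, cb$n_deviant, cb$n_standard))
  }
  invisible(x)
}
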