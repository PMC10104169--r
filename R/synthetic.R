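# Synthetic session generator. The animal recordings behind the analyses are
# not publicly deposited, so every estimator in the package is validated
# against sessions generated here with known ground truth: two-region LFPs
# with theta and gamma components, controllable theta-phase -> gamma-amplitude
# coupling, a controllable inter-regional lag, spike trains phase-locked to
# theta with set concentration, scripted object-visit schedules, and
# click/oddball tone streams with embedded evoked responses.

#' Ground truth for a synthetic session
#'
#' Parameterizes the statistical structure the downstream analyses assume.
#'
#' @param theta_freq theta frequency, Hz.
#' @param gamma_freq gamma frequency, Hz.
#' @param pac_depth fraction of the gamma amplitude modulated by theta phase,
#'   in \[0, 1\]. 0 means no coupling; 1 means the envelope reaches zero at the
#'   theta trough.
#' @param lag_ms signed region1 -> region2 delay in milliseconds (positive:
#'   region 1 leads).
#' @param kappa von Mises concentration of spike phase locking to theta
#'   (>= 0; `Inf` pins every spike to the preferred phase).
#' @param mu preferred firing phase, radians (0 = theta peak).
#' @param spike_rate mean firing rate, Hz.
#' @param aep_response_prob probability that a click trial carries an evoked
#'   response. Default 0.823, the baseline response ratio the analyses are
#'   benchmarked against.
#' @param mmn_extra_negativity extra negativity (microvolts) injected on
#'   deviant trials over a 100-ms window; negative values produce a mismatch
#'   negativity.
#' @param visit_schedule data frame with columns `label`, `start_s`, `end_s`:
#'   non-overlapping, ordered object visits.
#' @param theta_amp,gamma_amp component amplitudes, microvolts.
#' @param pink_sd,white_sd 1/f and white noise standard deviations, microvolts.
#' @param seed integer seed; the whole session is reproducible from it.
#' @return object of class `ground_truth` (a validated list).
#' @export
ground_truth <- function(theta_freq = 8, gamma_freq = 60, pac_depth = 0.5,
                         lag_ms = 0, kappa = 1, mu = 0, spike_rate = 25,
                         aep_response_prob = 0.823,
                         mmn_extra_negativity = -3,
                         visit_schedule = NULL,
                         theta_amp = 50, gamma_amp = 15,
                         pink_sd = 20, white_sd = 5,
                         seed = 1L) {
  stopifnot(pac_depth >= 0, pac_depth <= 1,
            aep_response_prob >= 0, aep_response_prob <= 1,
            kappa >= 0, theta_freq > 0, gamma_freq > 0, spike_rate >= 0)
  if (!is.null(visit_schedule) && nrow(visit_schedule) > 0L) {
    stopifnot(all(c("label", "start_s", "end_s") %in% names(visit_schedule)))
    vs <- visit_schedule[order(visit_schedule$start_s), ]
    if (any(vs$end_s <= vs$start_s)) stop("visit intervals must have end > start")
    if (nrow(vs) > 1L && any(vs$start_s[-1] < vs$end_s[-nrow(vs)])) {
      stop("visit intervals must be non-overlapping and ordered")
    }
    visit_schedule <- vs
  }
  structure(list(theta_freq = theta_freq, gamma_freq = gamma_freq,
                 pac_depth = pac_depth, lag_ms = lag_ms, kappa = kappa,
                 mu = mu, spike_rate = spike_rate,
                 aep_response_prob = aep_response_prob,
                 mmn_extra_negativity = mmn_extra_negativity,
                 visit_schedule = visit_schedule,
                 theta_amp = theta_amp, gamma_amp = gamma_amp,
                 pink_sd = pink_sd, white_sd = white_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' 1/f (pink) noise
#'
#' Spectrally shaped Gaussian noise with amplitude proportional to
#' `1/sqrt(f)`, the dominant background of extracellular field potentials.
#'
#' @param n number of samples.
#' @param sd target standard deviation.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, sd = 1) {
  if (n < 2L) return(stats::rnorm(n, 0, sd))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))              # avoid the DC singularity
  f <- pmin(f, n - f + 1)                # symmetric shaping
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used by the phase-locked spike generator
#' and as an independent phase source when validating the pairwise phase
#' consistency estimator.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0; 0 gives uniform phases).
#' @return phases in (-pi, pi\].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (is.infinite(kappa)) return(rep(mu, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

#' Generate a coupled two-region LFP
#'
#' The shared theta component is a stochastic narrowband oscillation
#' (band-pass filtered white noise, `theta_freq` +/- 2 Hz), not a pure
#' sinusoid: a deterministic sinusoid carries no phase-slope information
#' across frequencies, so a directional lag would be invisible to
#' cross-spectral estimators. Region 1 receives the theta plus an
#' unmodulated gamma component; region 2 receives the same theta delayed by
#' `lag_ms` plus a gamma component whose envelope follows the (delayed)
#' theta phase with depth `pac_depth`:
#' envelope = `gamma_amp * ((1 - d) + d * (1 + cos(phase)) / 2)`, maximal at
#' the theta peak. Both regions receive independent pink (1/f) and white
#' noise.
#'
#' @param gt a `ground_truth`.
#' @param duration_s session length, seconds (> 0).
#' @param fs_hz sampling rate, Hz (>= 1000).
#' @param seed optional override of `gt$seed`.
#' @return a `recording` with channels `r1` (mPFC) and `r2` (dHPC); the
#'   ground-truth theta phases are stored in `meta` for oracle checks.
#' @export
gen_coupled_lfp <- function(gt, duration_s, fs_hz = 1000, seed = gt$seed) {
  stopifnot(duration_s > 0, fs_hz >= 1000)
  max_lag <- 1000 / (4 * gt$theta_freq)
  if (abs(gt$lag_ms) > max_lag) {
    stop(sprintf(
      "|lag_ms| = %g exceeds a quarter theta period (%g ms): lead/lag sign ambiguous",
      abs(gt$lag_ms), max_lag))
  }
  set.seed(seed)
  n <- round(duration_s * fs_hz)
  t <- (0:(n - 1)) / fs_hz
  lag_smp <- round(gt$lag_ms / 1000 * fs_hz)
  off1 <- max(lag_smp, 0)
  off2 <- max(-lag_smp, 0)
  base <- bandpass_filter(stats::rnorm(n + abs(lag_smp)), fs_hz,
                          c(gt$theta_freq - 2, gt$theta_freq + 2))
  base <- base / stats::sd(base) * gt$theta_amp / sqrt(2)
  theta1 <- base[(1:n) + off1]
  theta2 <- base[(1:n) + off2]          # r2 lags r1 by lag_smp samples
  ph1 <- Arg(analytic_signal(theta1))
  ph2 <- Arg(analytic_signal(theta2))
  d <- gt$pac_depth
  env2 <- gt$gamma_amp * ((1 - d) + d * (1 + cos(ph2)) / 2)
  phg <- stats::runif(2, 0, 2 * pi)
  gamma1 <- gt$gamma_amp * cos(2 * pi * gt$gamma_freq * t + phg[1])
  gamma2 <- env2 * cos(2 * pi * gt$gamma_freq * t + phg[2])
  r1 <- theta1 + gamma1 + pink_noise(n, gt$pink_sd) +
    stats::rnorm(n, 0, gt$white_sd)
  r2 <- theta2 + gamma2 + pink_noise(n, gt$pink_sd) +
    stats::rnorm(n, 0, gt$white_sd)
  sig <- rbind(r1 = r1, r2 = r2)
  recording(sig, fs_hz, c("mPFC", "dHPC"),
            meta = list(ground_truth = gt, seed = seed,
                        theta_phase = list(r1 = ph1, r2 = ph2)))
}

#' Generate theta-phase-locked spikes
#'
#' Inhomogeneous point process with rate proportional to
#' `exp(kappa * cos(phase - mu))` and mean rate `spike_rate`, simulated by
#' thinning a homogeneous Poisson process. The driving phase is extracted
#' from the theta band of the requested LFP channel, so the spikes are locked
#' to what a downstream spike-phase analysis will actually measure.
#'
#' @param gt a `ground_truth`.
#' @param lfp a `recording` or `lfp_signal` containing a theta component.
#' @param channel channel index supplying the phase (default 2, the
#'   hippocampal channel of [gen_coupled_lfp()]).
#' @param theta_band band used to extract the driving phase, Hz.
#' @param seed optional override of `gt$seed`.
#' @return a `spike_train` with one channel.
#' @export
gen_phase_locked_spikes <- function(gt, lfp, channel = 2L,
                                    theta_band = c(gt$theta_freq - 2,
                                                   gt$theta_freq + 2),
                                    seed = gt$seed + 1L) {
  set.seed(seed)
  x <- lfp$signals[channel, ]
  fs <- lfp$fs
  dur <- length(x) / fs
  phase <- instantaneous_phase(x, fs, theta_band)
  if (is.infinite(gt$kappa)) {
    # spikes exactly at the preferred phase, one per theta cycle
    target <- ((phase - gt$mu + pi) %% (2 * pi)) - pi
    cross <- which(diff(sign(target)) > 0)   # upward zero crossings
    times <- (cross + 0.5) / fs
    return(spike_train(list(times), duration_s = dur))
  }
  i0k <- besselI(gt$kappa, 0, expon.scaled = TRUE) * exp(gt$kappa)
  lambda_max <- gt$spike_rate * exp(gt$kappa) / i0k
  n_cand <- stats::rpois(1, lambda_max * dur)
  cand <- sort(stats::runif(n_cand, 0, dur))
  ph_c <- stats::approx(seq_along(phase) / fs, unwrap_phase(phase),
                        xout = cand, rule = 2)$y
  rate <- gt$spike_rate * exp(gt$kappa * cos(ph_c - gt$mu)) / i0k
  keep <- stats::runif(n_cand) < rate / lambda_max
  times <- unique(cand[keep])
  spike_train(list(times), duration_s = dur)
}

# Unwrap wrapped phases so they can be linearly interpolated between samples.
unwrap_phase <- function(p) {
  dp <- diff(p)
  jump <- cumsum(c(0, -2 * pi * round(dp / (2 * pi))))
  p + jump
}

#' Generate a novel-object-recognition behavior session
#'
#' Builds the event table from the scripted visit schedule, a two-region LFP
#' for the whole session, and an accelerometer trace that is quiescent during
#' visits (the animal stands at the object) and active between them.
#'
#' @param gt a `ground_truth` with a non-empty `visit_schedule`.
#' @param fs_hz sampling rate, Hz.
#' @param tail_s seconds appended after the last visit.
#' @param seed optional override of `gt$seed`.
#' @return list with `recording` (signals + accelerometer + events) and
#'   `epochs` (the visit `epoch_set`).
#' @export
gen_behavior_session <- function(gt, fs_hz = 1000, tail_s = 10,
                                 seed = gt$seed) {
  vs <- gt$visit_schedule
  if (is.null(vs) || nrow(vs) == 0L) {
    rec <- gen_coupled_lfp(gt, duration_s = tail_s, fs_hz = fs_hz, seed = seed)
    rec$events <- data.frame(onset_s = numeric(), offset_s = numeric(),
                             label = character())
    return(list(recording = rec, epochs = epoch_set()))
  }
  dur <- max(vs$end_s) + tail_s
  rec <- gen_coupled_lfp(gt, duration_s = dur, fs_hz = fs_hz, seed = seed)
  n <- ncol(rec$signals)
  t <- (0:(n - 1)) / fs_hz
  in_visit <- rep(FALSE, n)
  for (i in seq_len(nrow(vs))) {
    in_visit[t >= vs$start_s[i] & t < vs$end_s[i]] <- TRUE
  }
  sd_axis <- ifelse(in_visit, 0.02, 0.3)
  accel <- rbind(stats::rnorm(n, 0, sd_axis),
                 stats::rnorm(n, 0, sd_axis),
                 stats::rnorm(n, 1, sd_axis))   # gravity on z
  rec$accel <- accel
  rec$events <- data.frame(onset_s = vs$start_s, offset_s = vs$end_s,
                           label = vs$label, stringsAsFactors = FALSE)
  list(recording = rec,
       epochs = epoch_set(vs$start_s, vs$end_s, vs$label))
}

# Slow LFP-like background for auditory sessions: band-limited 1-15 Hz
# noise. Evoked responses ride on the delta/theta-dominated field; a
# broadband background would make the fixed peak-over-baseline-SD detection
# rule fire on noise alone (the max of hundreds of independent samples
# crosses 3 SD with high probability), and unbounded 1/f drift defeats the
# per-trial baseline-SD estimate; neither is how evoked potentials present
# against the in-vivo field.
slow_background <- function(n, fs, sd) {
  x <- bandpass_filter(stats::rnorm(n), fs, c(1, 15))
  x / stats::sd(x) * sd
}

# Evoked-response template: Gaussian-windowed positive deflections at 55 ms
# (P2-like) and 250 ms (P3-like) post-stimulus.
erp_template <- function(t_s, p2_amp = 8, p3_amp = 5,
                         p2_center = 0.055, p2_sd = 0.008,
                         p3_center = 0.250, p3_sd = 0.030) {
  p2_amp * exp(-(t_s - p2_center)^2 / (2 * p2_sd^2)) +
    p3_amp * exp(-(t_s - p3_center)^2 / (2 * p3_sd^2))
}

#' Generate an auditory session (click train or oddball)
#'
#' `click_train`: 100 tone onsets 10 s apart; with probability
#' `aep_response_prob` a trial carries the evoked-response template (positive
#' deflections in the 40-70 ms and 200-300 ms windows) on top of the noise
#' background. `oddball`: 1000 tone events at 500 ms intervals, 10 ms tones of
#' two frequencies (6 and 8 kHz labels) in 75-25 percent proportions, roles
#' swapped after 500 trials (flip-flop); deviant trials carry an extra
#' deflection of `mmn_extra_negativity` microvolts spanning 70-170 ms.
#'
#' @param gt a `ground_truth`.
#' @param protocol `"click_train"` or `"oddball"`.
#' @param fs_hz sampling rate, Hz.
#' @param n_trials number of tone events (default 100 clicks / 1000 oddball
#'   tones).
#' @param isi_s inter-stimulus interval, seconds (default 10 clicks / 0.5
#'   oddball).
#' @param noise_sd background noise SD, microvolts.
#' @param seed optional override of `gt$seed`.
#' @return list with `recording` (single mPFC channel; `events` carries
#'   `onset_s`, `offset_s`, `label` and, for oddball, `freq_hz`, `role`,
#'   `block`), `epochs` (tone epochs), and `responsive` (click_train only:
#'   ground-truth response indicator per trial).
#' @export
gen_auditory_session <- function(gt, protocol = c("click_train", "oddball"),
                                 fs_hz = 1000,
                                 n_trials = NULL, isi_s = NULL,
                                 noise_sd = 2, seed = gt$seed) {
  protocol <- match.arg(protocol)
  set.seed(seed)
  if (protocol == "click_train") {
    if (is.null(n_trials)) n_trials <- 100L
    if (is.null(isi_s)) isi_s <- 10
    onsets <- 1 + (seq_len(n_trials) - 1L) * isi_s
    dur <- max(onsets) + 1
    n <- round(dur * fs_hz)
    x <- slow_background(n, fs_hz, noise_sd)
    responsive <- stats::runif(n_trials) < gt$aep_response_prob
    tpl_t <- seq(0, 0.5, by = 1 / fs_hz)
    tpl <- erp_template(tpl_t)
    for (k in which(responsive)) {
      i0 <- round(onsets[k] * fs_hz) + 1L
      idx <- i0:(i0 + length(tpl) - 1L)
      x[idx] <- x[idx] + tpl
    }
    ev <- data.frame(onset_s = onsets, offset_s = onsets + 0.015,
                     label = "click", stringsAsFactors = FALSE)
    rec <- recording(matrix(x, 1), fs_hz, "mPFC", events = ev,
                     meta = list(ground_truth = gt, seed = seed))
    return(list(recording = rec,
                epochs = epoch_set(ev$onset_s, ev$offset_s, ev$label),
                responsive = responsive))
  }
  # oddball flip-flop
  if (is.null(n_trials)) n_trials <- 1000L
  if (is.null(isi_s)) isi_s <- 0.5
  half <- n_trials %/% 2L
  freqs <- c(6000, 8000)
  role1 <- ifelse(stats::runif(half) < 0.25, "deviant", "standard")
  role2 <- ifelse(stats::runif(n_trials - half) < 0.25, "deviant", "standard")
  # block 1: 8 kHz standard / 6 kHz deviant; block 2: roles flipped
  f1 <- ifelse(role1 == "deviant", freqs[1], freqs[2])
  f2 <- ifelse(role2 == "deviant", freqs[2], freqs[1])
  onsets <- 1 + (seq_len(n_trials) - 1L) * isi_s
  dur <- max(onsets) + 1
  n <- round(dur * fs_hz)
  x <- slow_background(n, fs_hz, noise_sd)
  tpl_t <- seq(0, 0.4, by = 1 / fs_hz)
  tpl <- erp_template(tpl_t, p2_amp = 6, p3_amp = 3)
  mmn <- gt$mmn_extra_negativity *
    as.numeric(tpl_t >= 0.070 & tpl_t < 0.170)
  role <- c(role1, role2)
  freq <- c(f1, f2)
  block <- rep(1:2, c(half, n_trials - half))
  for (k in seq_len(n_trials)) {
    i0 <- round(onsets[k] * fs_hz) + 1L
    idx <- i0:(i0 + length(tpl) - 1L)
    add <- tpl
    if (role[k] == "deviant") add <- add + mmn
    x[idx] <- x[idx] + add
  }
  ev <- data.frame(onset_s = onsets, offset_s = onsets + 0.010,
                   label = role, freq_hz = freq, role = role, block = block,
                   stringsAsFactors = FALSE)
  rec <- recording(matrix(x, 1), fs_hz, "mPFC", events = ev,
                   meta = list(ground_truth = gt, seed = seed))
  list(recording = rec,
       epochs = epoch_set(ev$onset_s, ev$offset_s, ev$label))
}
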