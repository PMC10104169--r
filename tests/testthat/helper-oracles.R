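# Independent oracles used across the suite. These deliberately avoid the
# package's computation paths: brute-force pairwise sums, explicit histogram
# binning, closed-form circular statistics.

# O(N^2) pairwise phase consistency by direct double sum.
ppc_brute <- function(phases) {
  n <- length(phases)
  acc <- 0
  for (i in 1:(n - 1)) {
    acc <- acc + sum(cos(phases[i] - phases[(i + 1):n]))
  }
  2 * acc / (n * (n - 1))
}

# Closed-form expected PPC of a von Mises sample: squared mean resultant.
ppc_vonmises_expected <- function(kappa) {
  (besselI(kappa, 1) / besselI(kappa, 0))^2
}

# Direct-binning modulation index: explicit per-bin loop, cut()-based
# binning, hand-written entropy.
mi_direct <- function(phase, amp, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- cut(phase, breaks = edges, include.lowest = TRUE, labels = FALSE)
  means <- numeric(n_bins)
  for (b in 1:n_bins) {
    sel <- which(idx == b)
    means[b] <- if (length(sel)) sum(amp[sel]) / length(sel) else 0
  }
  p <- means / sum(means)
  h <- 0
  for (b in 1:n_bins) if (p[b] > 0) h <- h - p[b] * log(p[b])
  (log(n_bins) - h) / log(n_bins)
}

# Circular mean of phases.
circ_mean <- function(phases) Arg(sum(exp(1i * phases)))

# Circular SD (angular deviation) of phases.
circ_sd <- function(phases) sqrt(-2 * log(Mod(mean(exp(1i * phases)))))

# MUA test fixture: dense injected spikes at -8 robust-sigma in white noise.
# Returns the recording, injected spike times, and the waveform used.
make_mua_fixture <- function(seed, fs = 20000, dur = 0.5, n_spikes = 100) {
  set.seed(seed)
  t <- seq(0, 0.0015, by = 1 / fs)
  shape <- -exp(-((t - 0.0004) / 0.00015)^2) +
    0.4 * exp(-((t - 0.0009) / 0.0003)^2)
  noise <- rnorm(fs * dur)
  s0 <- median(abs(bandpass_filter(noise, fs, c(450, 6000)))) / 0.6745
  pos <- round(seq(0.03, dur - 0.03, length.out = n_spikes) * fs) +
    sample(-20:20, n_spikes, replace = TRUE)
  x <- noise
  for (i0 in pos) {
    x[i0:(i0 + length(shape) - 1)] <- x[i0:(i0 + length(shape) - 1)] +
      8 * s0 * shape
  }
  list(rec = recording(matrix(x, 1), fs, "mPFC"),
       inj_times = (pos - 1) / fs, shape = shape)
}

# Recall and precision of detected vs injected times with a matching window.
match_spikes <- function(detected, injected, tol_s = 0.002) {
  recall <- mean(vapply(injected,
                        function(ti) any(abs(detected - ti) < tol_s),
                        logical(1)))
  fp <- sum(vapply(detected,
                  function(td) !any(abs(injected - td) < tol_s),
                  logical(1)))
  list(recall = recall,
       precision = (length(detected) - fp) / length(detected))
}

# FFT phase randomization: destroys cross-frequency structure, keeps the
# power spectrum.
phase_scramble <- function(x, seed = 1) {
  set.seed(seed)
  n <- length(x)
  X <- stats::fft(x)
  half <- 2:ceiling(n / 2)
  ph <- runif(length(half), 0, 2 * pi)
  X[half] <- Mod(X[half]) * exp(1i * ph)
  X[n - half + 2] <- Conj(X[half])
  Re(stats::fft(X, inverse = TRUE) / n)
}
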