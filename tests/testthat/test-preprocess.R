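# LFP extraction, MUA threshold crossing, rest detection, rate binning.

test_that("LFP extraction preserves passband signals and removes trends", {
  fs <- 30000
  t <- (0:(fs * 5 - 1)) / fs
  s <- 10 * sin(2 * pi * 10 * t)
  lfp <- extract_lfp(recording(matrix(s, 1), fs, "mPFC"))
  expect_equal(lfp$fs, 1000)
  core <- lfp$signals[1, 1000:4000]
  expect_equal(sqrt(2) * sd(core), 10, tolerance = 0.01)  # amplitude within 1 %
  # linear ramp removed
  ramp <- s + seq(0, 100, length.out = length(s))
  lfp_r <- extract_lfp(recording(matrix(ramp, 1), fs, "mPFC"))
  fit <- coef(lm(y ~ x, data.frame(y = lfp_r$signals[1, ],
                                   x = seq_len(ncol(lfp_r$signals)))))
  orig_slope <- 100 / length(s)
  expect_lt(abs(fit[2]) / (orig_slope * 30), 1e-3)
})

test_that("the notch attenuates mains contamination by at least 20 dB", {
  fs <- 30000
  t <- (0:(fs * 5 - 1)) / fs
  theta <- 5 * sin(2 * pi * 8 * t)
  mains <- 50 * sin(2 * pi * 50 * t)   # 10x theta amplitude
  power_at <- function(x, fs, f0) {
    n <- length(x)
    k <- round(f0 * n / fs) + 1
    Mod(fft(x)[k])^2 / n
  }
  lfp <- extract_lfp(recording(matrix(theta + mains, 1), fs, "mPFC"))
  p_after <- power_at(lfp$signals[1, ], 1000, 50)
  lfp_no <- extract_lfp(recording(matrix(theta + mains, 1), fs, "mPFC"),
                        notch_hz = NA)
  p_before <- power_at(lfp_no$signals[1, ], 1000, 50)
  expect_gt(10 * log10(p_before / p_after), 20)
  # theta untouched (50 Hz component removed, 8 Hz amplitude intact)
  theta_only <- bandpass_filter(lfp$signals[1, ], 1000, c(6, 10))
  expect_equal(sqrt(2) * sd(theta_only[1000:4000]), 5, tolerance = 0.05)
})

test_that("non-integer decimation ratios resample with a warning", {
  fs <- 2500
  s <- sin(2 * pi * 10 * (0:(fs * 2 - 1)) / fs)
  expect_warning(lfp <- extract_lfp(recording(matrix(s, 1), fs, "mPFC")),
                 "resampling")
  expect_equal(lfp$fs, 1000)
})

test_that("decimation preserves sub-200 Hz band power within 5 percent", {
  set.seed(8)
  fs <- 30000
  x <- pink_noise(fs * 10, 30)
  ps_raw <- multitaper_psd(lfp_signal(matrix(x, 1), fs, "mPFC"), NULL)
  lfp <- extract_lfp(recording(matrix(x, 1), fs, "mPFC"), notch_hz = NA)
  ps_dec <- multitaper_psd(lfp, NULL)
  for (band in list(c(2, 5), c(8, 12), c(52, 100), c(100, 200))) {
    r <- band_power(ps_dec, band_name = band) /
      band_power(ps_raw, band_name = band)
    expect_equal(r, 1, tolerance = 0.05)
  }
})

test_that("MUA extraction recovers injected -8 sigma spikes", {
  fx <- make_mua_fixture(seed = 7)
  st <- extract_mua(fx$rec)
  m <- match_spikes(st$spike_times[[1]], fx$inj_times)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  expect_error(extract_mua(fx$rec, channel = 1, reference_channel = 1),
               "differ")
})

test_that("pure-noise detections match the Gaussian crossing rate within 2x", {
  set.seed(9)
  fs <- 20000
  x <- rnorm(fs * 5)
  st <- extract_mua(recording(matrix(x, 1), fs, "mPFC"))
  observed_rate <- length(st$spike_times[[1]]) / 5
  # Rice rate at -3 sigma for the 450-6000 Hz band of white noise
  a <- 450; b <- 6000
  nu0 <- sqrt((b^3 - a^3) / (3 * (b - a)))
  expected <- nu0 * exp(-9 / 2)
  expect_gt(observed_rate, expected / 2)
  expect_lt(observed_rate, expected * 2)
})

test_that("common-mode artifacts cancel through reference subtraction", {
  set.seed(10)
  fs <- 20000
  n <- fs * 2
  artifact <- numeric(n)
  for (i0 in seq(fs %/% 4, n - fs %/% 4, by = fs %/% 2)) {
    artifact[i0:(i0 + 200)] <- -50
  }
  noise_a <- rnorm(n, 0, 0.5)
  rec <- recording(rbind(artifact + noise_a, artifact + rnorm(n, 0, 0.5)),
                   fs, c("mPFC", "mPFC"))
  st_ref <- extract_mua(rec, channel = 1, reference_channel = 2)
  # with the artifact cancelled, detections match a noise-only trace's rate
  st_noise <- extract_mua(recording(matrix(noise_a - rnorm(n, 0, 0.5), 1),
                                    fs, "mPFC"))
  n_ref <- length(st_ref$spike_times[[1]])
  n_noise <- length(st_noise$spike_times[[1]])
  expect_lt(abs(n_ref - n_noise), 0.5 * n_noise)
})

test_that("rest detection applies the 2-10 s rule and 3-s tiling", {
  set.seed(11)
  fs <- 100
  quiet_sd <- 0.01; active_sd <- 0.5
  sd_profile <- function(spans, dur) {
    s <- rep(active_sd, dur * fs)
    for (sp in spans) s[(sp[1] * fs + 1):(sp[2] * fs)] <- quiet_sd
    s
  }
  make_rec <- function(spans, dur) {
    s <- sd_profile(spans, dur)
    accel <- rbind(rnorm(length(s), 0, s), rnorm(length(s), 0, s),
                   rnorm(length(s), 1, s))
    recording(matrix(rnorm(length(s)), 1), fs, "mPFC", accel = accel)
  }
  # threshold between the quiet (~1e-4) and active (~0.25) variance clusters;
  # the percentile default targets sessions where rest is a minority of time
  thr <- 0.01
  # quiet 0-5 s and 20-24 s, active in between
  ep <- detect_rest_epochs(make_rec(list(c(0, 5), c(20, 24)), 24),
                           threshold = thr)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$start_s, c(0, 20), tolerance = 0.5)
  expect_equal(ep$end_s, c(5, 24), tolerance = 0.5)
  # a 1.5-s quiet run is too short
  ep2 <- detect_rest_epochs(make_rec(list(c(10, 11.5)), 30), threshold = thr)
  expect_equal(nrow(ep2), 0)
  # a 14-s run is retained, split to <= 10 s, and tiles into 4 windows of 3 s
  ep3 <- detect_rest_epochs(make_rec(list(c(5, 19)), 40), threshold = thr)
  expect_true(all(ep3$end_s - ep3$start_s <= 10 + 1e-9))
  expect_equal(sum(ep3$end_s - ep3$start_s), 14, tolerance = 1)
  expect_equal(nrow(tile_epochs(ep3, 3)), 4)
  # all-zero accelerometer warns
  zero_rec <- recording(matrix(rnorm(fs * 30), 1), fs, "mPFC",
                        accel = matrix(0, 3, fs * 30))
  expect_warning(detect_rest_epochs(zero_rec), "all-zero")
})

test_that("rest epochs avoid event-marked exploration intervals", {
  set.seed(12)
  vs <- data.frame(label = c("novel", "familiar"),
                   start_s = c(10, 20), end_s = c(14, 25))
  ses <- gen_behavior_session(ground_truth(visit_schedule = vs, seed = 12))
  overlap_s <- function(ep) {
    tot <- 0
    for (i in seq_len(nrow(ep))) {
      for (j in seq_len(nrow(vs))) {
        tot <- tot + max(0, min(ep$end_s[i], vs$end_s[j]) -
                           max(ep$start_s[i], vs$start_s[j]))
      }
    }
    tot
  }
  # low mobility occurs only at the objects here, so excluding the
  # event-marked intervals leaves no rest overlapping a visit
  ep <- detect_rest_epochs(ses$recording)
  expect_equal(overlap_s(ep), 0)
  # without the exclusion the quiescent visit periods are (wrongly) rest
  ep_raw <- detect_rest_epochs(ses$recording, exclude_events = FALSE)
  expect_gt(overlap_s(ep_raw), 2)
})

test_that("firing-rate binning divides counts by the window", {
  st <- spike_train(list(seq(0.05, 2.95, length.out = 30)), duration_s = 3)
  expect_equal(as.numeric(bin_firing_rate(st, 3)), 10)
  empty <- spike_train(list(numeric()), duration_s = 9)
  expect_equal(as.numeric(bin_firing_rate(empty, 3)), c(0, 0, 0))
  set.seed(13)
  pois <- spike_train(list(sort(runif(2000, 0, 100))), duration_s = 100)
  r <- bin_firing_rate(pois, 3)
  expect_equal(mean(r), 20, tolerance = 3 * sqrt(20 / (3 * length(r))) / 20)
})
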