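# Synthetic-session generator: determinism, parameter validation, and
# recoverability of the injected ground truth.

test_that("same seed gives bit-identical LFPs; lag bound is enforced", {
  gt <- ground_truth(lag_ms = 10, seed = 11)
  a <- gen_coupled_lfp(gt, 5, 1000)
  b <- gen_coupled_lfp(gt, 5, 1000)
  expect_identical(a$signals, b$signals)
  # quarter theta period at 8 Hz is 31.25 ms
  gt_bad <- ground_truth(theta_freq = 8, lag_ms = 40)
  expect_error(gen_coupled_lfp(gt_bad, 5, 1000), "quarter theta period")
})

test_that("ground truth validates its invariants", {
  expect_error(ground_truth(pac_depth = 1.5))
  expect_error(ground_truth(kappa = -1))
  expect_error(ground_truth(aep_response_prob = 2))
  vs <- data.frame(label = c("novel", "familiar"),
                   start_s = c(0, 1), end_s = c(2, 3))
  expect_error(ground_truth(visit_schedule = vs), "non-overlapping")
})

test_that("uncoupled sessions show no PAC above a phase-scrambled control", {
  hits <- vapply(1:6, function(s) {
    rec <- gen_coupled_lfp(ground_truth(pac_depth = 0, seed = s), 30, 1000)
    x <- rec$signals[2, ]
    mi <- modulation_index(x, x, 1000, c(6, 10), c(50, 70))
    mi_null <- modulation_index(x, phase_scramble(x, seed = s), 1000,
                                c(6, 10), c(50, 70))
    mi > 5 * mi_null
  }, logical(1))
  expect_lt(mean(hits), 0.5)
})

test_that("phase-locked spikes recover kappa through the PPC", {
  # spikes cluster within theta cycles, so the effective sample size is the
  # cycle count, not the spike count: average over seeds
  ppc_hat <- mean(vapply(1:3, function(s) {
    gt <- ground_truth(kappa = 1, spike_rate = 40, seed = s)
    rec <- gen_coupled_lfp(gt, 40, 1000)
    st <- gen_phase_locked_spikes(gt, rec)
    ph <- spike_phases(st, lfp_signal(rec$signals, 1000, rec$regions),
                       c(6, 10), channel = 2)
    expect_gt(length(ph), 500)
    ppc(ph)
  }, numeric(1)))
  expect_lt(abs(ppc_hat - ppc_vonmises_expected(1)), 0.035)
  gt <- ground_truth(kappa = 1, spike_rate = 40, seed = 2)
  rec <- gen_coupled_lfp(gt, 40, 1000)
  lfp <- lfp_signal(rec$signals, 1000, rec$regions)
  # kappa = 0: no locking
  st0 <- gen_phase_locked_spikes(ground_truth(kappa = 0, spike_rate = 40,
                                              seed = 2), rec)
  ph0 <- spike_phases(st0, lfp, c(6, 10), channel = 2)
  expect_lt(abs(ppc(ph0)), 2 / sqrt(length(ph0)))
  # kappa = Inf: every spike at the preferred phase
  stI <- gen_phase_locked_spikes(ground_truth(kappa = Inf, seed = 2), rec)
  phI <- spike_phases(stI, lfp, c(6, 10), channel = 2)
  expect_gt(ppc(phI), 0.97)
  expect_true(all(diff(stI$spike_times[[1]]) > 0))
})

test_that("behavior sessions carry the scripted visits and a consistent accelerometer", {
  vs <- data.frame(label = c("novel", "familiar", "novel"),
                   start_s = c(5, 12, 20), end_s = c(8, 15, 22))
  gt <- ground_truth(visit_schedule = vs, seed = 3)
  ses <- gen_behavior_session(gt)
  expect_s3_class(ses$epochs, "epoch_set")
  expect_equal(nrow(ses$epochs), 3)
  expect_equal(ses$recording$events$onset_s, vs$start_s)
  acc <- ses$recording$accel
  mod <- sqrt(colSums(acc^2))
  fs <- ses$recording$fs
  in_visit <- var(mod[(6 * fs):(7 * fs)])     # inside first visit
  between <- var(mod[(9 * fs):(11 * fs)])     # between visits
  expect_gt(between, 10 * in_visit)
  # empty schedule degenerates cleanly
  ses0 <- gen_behavior_session(ground_truth(seed = 3))
  expect_equal(nrow(ses0$epochs), 0)
})

test_that("click sessions embed responses at the stated probability and spacing", {
  gt <- ground_truth(aep_response_prob = 1, seed = 4)
  ses <- gen_auditory_session(gt, "click_train", noise_sd = 0.01,
                              n_trials = 20)
  expect_equal(nrow(ses$recording$events), 20)
  expect_equal(unique(diff(ses$recording$events$onset_s)), 10)
  expect_true(all(ses$responsive))
  trials <- epoch_trials(lfp_signal(ses$recording$signals, 1000, "mPFC"),
                         ses$recording$events)
  det <- detect_aep(trials)
  expect_equal(det$response_ratio, 1.0)
})

test_that("oddball sessions are flip-flop frequency-matched by construction", {
  gt <- ground_truth(seed = 5)
  ses <- gen_auditory_session(gt, "oddball", n_trials = 400)
  ev <- ses$recording$events
  expect_equal(nrow(ev), 400)
  # within each block one frequency is exclusively deviant, the other
  # exclusively standard, and roles swap across blocks
  for (b in 1:2) {
    evb <- ev[ev$block == b, ]
    tab <- table(evb$freq_hz, evb$role)
    expect_true(all(rowSums(tab > 0) == 1))
  }
  dev1 <- unique(ev$freq_hz[ev$block == 1 & ev$role == "deviant"])
  dev2 <- unique(ev$freq_hz[ev$block == 2 & ev$role == "deviant"])
  expect_false(dev1 == dev2)
  # deviants are the rare category (~25 percent)
  expect_equal(mean(ev$role == "deviant"), 0.25, tolerance = 0.2)
})

test_that("recordings round-trip through the binary + sidecar format", {
  gt <- ground_truth(seed = 6)
  rec <- gen_coupled_lfp(gt, 2, 1000)
  prefix <- file.path(tempdir(), "roundtrip")
  write_recording(rec, prefix)
  back <- read_recording(prefix)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$regions, rec$regions)
  # int16 quantization at 0.195 uV/bit
  expect_lt(max(abs(back$signals - rec$signals)), 0.195)
  write_ground_truth(gt, file.path(tempdir(), "gt.json"))
  gt_back <- jsonlite::read_json(file.path(tempdir(), "gt.json"),
                                 simplifyVector = TRUE)
  expect_equal(gt_back$theta_freq, gt$theta_freq)
})
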