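# Trial epoching, AEP detection, component metrics, MMN.

test_that("trial epoching baseline-corrects and drops edge trials", {
  fs <- 1000
  lfp <- lfp_signal(matrix(rep(7, fs * 30), 1), fs, "mPFC")  # constant offset
  ev <- data.frame(onset_s = seq(2, 28, by = 3))
  trials <- epoch_trials(lfp, ev)
  expect_equal(nrow(trials), length(ev$onset_s))
  expect_true(all(abs(trials) < 1e-12))   # offset removed entirely
  ev_edge <- data.frame(onset_s = c(0.1, 5, 29.9))
  expect_warning(tr2 <- epoch_trials(lfp, ev_edge), "dropped")
  expect_equal(nrow(tr2), 1)
})

test_that("the mean ERP recovers the injected template at low noise", {
  gt <- ground_truth(aep_response_prob = 1, seed = 111)
  ses <- gen_auditory_session(gt, "click_train", noise_sd = 0.05,
                              n_trials = 30)
  lfp <- lfp_signal(ses$recording$signals, 1000, "mPFC")
  trials <- epoch_trials(lfp, ses$recording$events)
  t_ms <- attr(trials, "time_ms")
  tpl <- circuitsync:::erp_template(pmax(t_ms, 0) / 1000)
  tpl[t_ms < 0] <- 0
  expect_gt(cor(colMeans(trials), tpl), 0.95)
})

test_that("AEP detection tracks the injected response probability", {
  ratios <- vapply(1:5, function(s) {
    ses <- gen_auditory_session(ground_truth(aep_response_prob = 0.8,
                                             seed = 120 + s), "click_train")
    lfp <- lfp_signal(ses$recording$signals, 1000, "mPFC")
    detect_aep(epoch_trials(lfp, ses$recording$events))$response_ratio
  }, numeric(1))
  expect_equal(mean(ratios), 0.8, tolerance = 0.08)
  # degenerate baseline errors
  lfp0 <- lfp_signal(matrix(0, 1, 10000), 1000, "mPFC")
  tr0 <- epoch_trials(lfp0, data.frame(onset_s = c(2, 5)))
  expect_error(detect_aep(tr0), "zero-variance")
})

test_that("pure-noise false-positive rate matches the Gaussian-tail oracle", {
  set.seed(112)
  fs <- 1000
  lfp <- lfp_signal(matrix(rnorm(fs * 1100), 1), fs, "mPFC")  # white noise
  ev <- data.frame(onset_s = seq(2, 1090, by = 10))
  det <- detect_aep(epoch_trials(lfp, ev))
  # peak of |x| over m iid samples vs 3 * estimated baseline SD
  m <- sum(attr(epoch_trials(lfp, ev), "time_ms") >= 10 &
             attr(epoch_trials(lfp, ev), "time_ms") < 350)
  p_analytic <- 1 - (1 - 2 * pnorm(-3))^m
  expect_equal(det$response_ratio, p_analytic, tolerance = 0.15)
})

test_that("component metrics are linear in template amplitude and windowed correctly", {
  fs <- 1000
  t <- seq(0, 0.5, by = 1 / fs)
  make_trials <- function(amp) {
    tpl <- circuitsync:::erp_template(t, p2_amp = amp, p3_amp = amp * 0.6)
    x <- numeric(fs * 60)
    on <- seq(2, 55, by = 2)
    for (o in on) {
      i0 <- round(o * fs) + 1
      x[i0:(i0 + length(tpl) - 1)] <- x[i0:(i0 + length(tpl) - 1)] + tpl
    }
    x <- x + rnorm(length(x), 0, 0.02)
    epoch_trials(lfp_signal(matrix(x, 1), fs, "mPFC"),
                 data.frame(onset_s = on))
  }
  set.seed(113)
  tr5 <- make_trials(5)
  m5 <- component_metrics(tr5, "P2")
  expect_equal(m5$amplitude, 5, tolerance = 0.1)      # within 10 %
  tr10 <- make_trials(10)
  m10 <- component_metrics(tr10, "P2")
  expect_equal(m10$amplitude / m5$amplitude, 2, tolerance = 0.05)
  p3_ratio <- component_metrics(tr10, "P3")$amplitude /
    component_metrics(tr5, "P3")$amplitude
  expect_equal(p3_ratio, 2, tolerance = 0.05)
  # spikes only in 200-300 ms: P3 rate positive, P2 rate zero
  on <- attr(tr5, "events")$onset_s
  spk <- spike_train(list(sort(c(on + 0.25, on + 0.27))), duration_s = 60)
  expect_equal(component_metrics(tr5, "P2", spikes = spk)$firing_rate, 0)
  expect_gt(component_metrics(tr5, "P3", spikes = spk)$firing_rate, 0)
})

test_that("the difference wave is exactly zero when deviant equals standard", {
  fs <- 1000
  t <- seq(0, 0.4, by = 1 / fs)
  tpl <- circuitsync:::erp_template(t, p2_amp = 6, p3_amp = 3)
  x <- numeric(fs * 120)
  ev <- data.frame(onset_s = 2 + 0.5 * (0:199))
  n <- nrow(ev)
  ev$freq_hz <- rep(c(6000, 8000), n / 2)
  ev$role <- rep(c("deviant", "standard"), each = n / 2)
  ev$block <- rep(1:2, each = n / 2)
  # both roles get the identical response
  for (o in ev$onset_s) {
    i0 <- round(o * fs) + 1
    x[i0:(i0 + length(tpl) - 1)] <- x[i0:(i0 + length(tpl) - 1)] + tpl
  }
  # frequency-matched flip-flop: make 6 kHz standard in block 2, deviant in 1
  ev$freq_hz <- ifelse(ev$block == 1,
                       ifelse(ev$role == "deviant", 6000, 8000),
                       ifelse(ev$role == "deviant", 8000, 6000))
  res <- mmn_analysis(lfp_signal(matrix(x, 1), fs, "mPFC"), ev)
  for (cb in res$combinations) {
    expect_lt(max(abs(cb$difference_wave)), 1e-6)
    expect_lt(abs(cb$auc), 1e-4)
  }
})

test_that("injected deviant negativity is recovered in the AUC", {
  ses <- gen_auditory_session(ground_truth(mmn_extra_negativity = -3,
                                           seed = 114), "oddball",
                              noise_sd = 0.5)
  res <- mmn_analysis(lfp_signal(ses$recording$signals, 1000, "mPFC"),
                      ses$recording$events)
  expect_equal(length(res$combinations), 2)
  for (cb in res$combinations) {
    # -3 uV over 100 ms inside the 40-200 ms window: AUC ~ -300 uV*ms
    expect_equal(cb$auc, -300, tolerance = 0.25)
    expect_lt(cb$auc, 0)
  }
  # shuffled labels: AUC collapses toward zero
  ev <- ses$recording$events
  set.seed(115)
  ev$role <- sample(ev$role)
  ev$freq_hz <- ifelse(ev$block == 1,
                       ifelse(ev$role == "deviant", 6000, 8000),
                       ifelse(ev$role == "deviant", 8000, 6000))
  res_sh <- mmn_analysis(lfp_signal(ses$recording$signals, 1000, "mPFC"), ev)
  for (cb in res_sh$combinations) {
    expect_lt(abs(cb$auc), 100)
  }
})
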