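---
title: "Quantifying prefrontal-hippocampal circuit dynamics with circuitsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prefrontal-hippocampal circuit dynamics with circuitsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitsync)
```

## The problem

Recognition memory and auditory processing in the mouse depend on
coordinated activity between the medial prefrontal cortex (mPFC) and the
dorsal hippocampus (dHPC). In NMDA-receptor hypofunction models of
schizophrenia, this coordination degrades: local oscillatory power shifts,
theta-gamma coupling weakens, and the directed flow of information between
the regions is disrupted. Detecting these changes requires a chain of
estimators — spectral power, cross-frequency coupling, directed
connectivity, spike-field locking, behavioral scoring, and evoked-potential
quantification — each of which has failure modes that are invisible unless
the estimator is exercised on data with known ground truth.

`circuitsync` implements that chain for dual-site (mPFC, dHPC) extracellular
recordings with accelerometer and TTL event streams, and pairs it with a
synthetic-session generator whose every effect size is dialed in explicitly.
Every estimator in the package is validated by recovering what the generator
injected.

## The synthetic generator: what it emulates and what it does not

`ground_truth()` fixes the statistical structure of a session, and the
`gen_*` functions realize it:

* **Two-region LFPs** (`gen_coupled_lfp`). The shared theta component is a
  *stochastic narrowband* oscillation (band-passed white noise at
  `theta_freq` ± 2 Hz), not a sinusoid. This matters: a deterministic tone
  has energy at a single frequency, so the cross-spectral phase has no slope
  and a directional lag is invisible to the phase slope index. Region 2
  receives the theta delayed by `lag_ms` (positive = mPFC leads); its gamma
  envelope follows the delayed theta phase as
  `gamma_amp * ((1 - d) + d (1 + cos phi)/2)` with `d = pac_depth`, so `d`
  runs from no coupling to full envelope modulation with the maximum at the
  theta peak. Both regions get independent pink (1/f) and white noise —
  the background that entropy-based coupling estimators must survive.
* **Phase-locked spikes** (`gen_phase_locked_spikes`): an inhomogeneous
  point process with rate proportional to `exp(kappa cos(phi - mu))`,
  simulated by thinning. `kappa` is the von Mises concentration the
  pairwise phase consistency should recover; `kappa = Inf` pins one spike
  per theta cycle at the preferred phase.
* **Behavior sessions** (`gen_behavior_session`): scripted object visits
  become the event table; the accelerometer is quiescent *during* visits
  (the animal stands at the object) and active between them.
* **Auditory sessions** (`gen_auditory_session`): a click train (100 tones,
  10 s apart) in which each trial carries the evoked-response template with
  probability `aep_response_prob`, and a flip-flop oddball (1000 tones,
  500 ms apart, 75/25 standard/deviant, roles swapped at trial 500) in
  which deviants carry an extra deflection of `mmn_extra_negativity`
  microvolts spanning 70-170 ms. The background here is band-limited
  1-15 Hz noise: evoked potentials ride on the slow field, and an unbounded
  1/f drift would defeat any per-trial baseline estimate, while a broadband
  background would make *any* fixed peak-over-baseline detector fire on
  noise alone (the maximum of hundreds of independent samples exceeds three
  baseline SDs with high probability).

Defaults are the conditions the validation suite runs under: theta 8 Hz,
gamma 60 Hz, `pac_depth` 0.5, `kappa` 1, 25 spikes/s, theta amplitude 50
microvolts over a 20-microvolt pink background, and `aep_response_prob`
0.823 so a default click session lands near the 82% response ratio regime
typical of healthy cortex.

What the generator does **not** emulate: biophysical network dynamics,
electrode drift and movement artifacts beyond a common-mode term, spike
waveform diversity (the package analyzes multi-unit threshold crossings,
not sorted units), volume conduction, and non-stationarity across a
session. Passing tests therefore certify the *estimators*, not the
hardware-facing robustness of a full experimental pipeline.

## Preprocessing

`extract_lfp` detrends, notch-filters (biquad, Q = 30, default 50 Hz,
applied forward-backward) and decimates to 1 kHz with staged zero-phase
Butterworth anti-aliasing at 0.8 x the target Nyquist; sub-200 Hz band
power — all analysis bands — survives within 5%. Non-integer rate ratios
fall back to interpolation with a warning.

`extract_mua` subtracts a reference channel (cancelling common-mode
movement artifacts), band-passes 450-6000 Hz, estimates sigma robustly as
`median(|x|)/0.6745`, and takes negative crossings at -3 sigma with a 1 ms
lockout. Two properties are worth stating plainly. First, on any Gaussian
trace the -3 sigma crossing rate is scale-free and substantial (the Rice
rate, roughly `nu0 exp(-4.5)`), so threshold crossings on quiet noise are
*expected* — they are what multi-unit activity is. Second, the robust sigma
deliberately resists spike contamination; on spike-dense traces it reads
the noise floor below the spikes, which is what makes near-perfect recall
and precision of large injected spikes attainable in the validation
fixture (100 spikes over 0.5 s, a realistic multi-unit rate).

`detect_rest_epochs` computes the variance of the acceleration module
`sqrt(x^2 + y^2 + z^2)` in 0.5-s windows (50% overlap) and keeps
sub-threshold runs of 2-10 s; longer runs are split rather than discarded.
The threshold is a session percentile (default 20th) because rest occupies
a minority of an open-field session; when the quiet/active split is known,
an absolute threshold can be passed instead. Event-marked intervals are
excluded by default so "rest" never doubles as task time — the generator
makes visits quiescent, and without the exclusion they would be classified
as rest. Epochs are tiled into 3-s windows for spectral analysis by
`tile_epochs`.

## Spectral estimation

`multitaper_psd` uses DPSS (Slepian) tapers with NW = 3 and 5 tapers —
a +/-1 Hz half-bandwidth on the 3-s windows the rest analysis uses. The
tapers are the top eigenvectors of the classic symmetric tridiagonal
matrix that commutes with the concentration operator, computed by Sturm
bisection plus inverse iteration and cached per window length; windows
longer than 8192 samples interpolate from a base solution, the standard
low-memory construction. Band powers integrate the PSD over half-open
bands (delta 2-5, slow theta 4-8, theta 8-12, low gamma 30-48, high gamma
52-100, HFO 100-200 Hz) with edge interpolation so the result does not
depend on grid alignment; the slow-theta/theta overlap at 8 Hz is a
property of the band scheme itself, and a combined 4-12 Hz `theta_wide`
band is provided for analyses quoted over "theta frequencies".
`spectrogram` is a plain consecutive-FFT short-time transform.

## Phase-amplitude coupling

`modulation_index` is the entropy-based statistic: band-pass both signals
(zero phase), take the phase of the slow signal and the envelope of the
fast one from their analytic signals, average the envelope in 18 phase
bins, normalize to a distribution `P`, and return
`(log N - H(P)) / log N`. It is 0 for phase-independent amplitude and 1
for single-bin concentration. Filtering below 1% of the sampling rate
switches from Butterworth to a linear-phase windowed-sinc FIR: IIR
cascades are numerically unstable at such low normalized frequencies (a
4th-order band-pass at 1-4 Hz on 1 kHz data diverges), and FIR filtering
is the convention for slow-band phase extraction anyway.

`comodulogram` evaluates the MI over phase centers 2-15 Hz (1 Hz step,
4 Hz bandwidth; the nominal 0 and 1 Hz centers would give degenerate
bands, so the effective grid starts at 2 Hz with the lower edge clipped at
1 Hz) by amplitude centers 10-250 Hz (5 Hz step, 10 Hz bandwidth, clipped
at Nyquist). One consequence of the fixed 10 Hz amplitude bandwidth is
worth knowing: an 8 Hz modulation of a 60 Hz carrier puts sidebands at
52 and 68 Hz, *outside* a 55-65 Hz band, so on-grid MI at the carrier
center is attenuated and the comodulogram peak can land one grid step off
the carrier. Quantitative MI work should use an amplitude band wide
enough to include the sidebands (e.g. 50-70 Hz for 8 Hz on 60 Hz), which
is why `modulation_index` takes explicit bands. `pac_quantify` averages a
rectangular region of interest of grid centers — the region is always an
explicit argument because different analyses read out different regions
(6-10 x 40-60 Hz, 7-10 x 60-80 Hz). `interregional_pac` draws phase and
amplitude from different regions.

## Directed connectivity: phase slope index

`phase_slope_index` cuts the data into 60-s epochs and 1-s Hanning
segments (50% overlap), averages segment cross-spectra per epoch, forms
the complex coherency `C(f)`, and accumulates
`Im(conj(C(f)) C(f + df))` over the band. A positive value means the
first signal leads; antisymmetry `psi(a,b) = -psi(b,a)` is exact by
construction. Visit-based analyses concatenate the 5-s visit epochs and
use the full concatenated length as the epoch, since behavioral visits
are far shorter than 60 s.

Significance uses a shuffle surrogate (`psi_surrogate`): on each of 1000
draws a random channel pair is taken and the second region's signal is
randomized — by a random circular time shift (default) or by permuting
epoch order; both read the "shuffle across time series and across channel
pairs" recipe, and the scheme is a named argument because the two differ
when epochs are few. The surrogate mean is subtracted from the raw PSI to
remove chance effects (`psi_corrected`), and a two-sided t-test of the
epoch-level PSI values against the surrogate distribution gives the
p-value (`psi_significance`), with an exact-equality fast path for
degenerate variances. The type-I rate of the full procedure on
independent noise is checked at alpha = 0.05 in the acceptance suite.

## Spike-field coupling

`spike_phases` reads the band-limited analytic-signal phase at spike times
(linear interpolation of the real and imaginary parts — interpolating the
wrapped angle itself would tear at the wrap). `ppc` is the pairwise phase
consistency `2/(N(N-1)) sum_{i<j} cos(theta_i - theta_j)`, computed via
the algebraic identity `((N R)^2 - N)/(N(N-1))`; unlike the squared
resultant it is unbiased at any N, which the suite verifies at N = 250.
`ppc_by_epochs` applies the operational rule: 25-s epochs, at least 250
spikes per epoch, sparser epochs reported as NA. For spike-delta
analyses the 3-6 Hz band is passed explicitly rather than the scheme's
2-5 Hz delta; both are available because the band is an argument.

One subtlety for validation: spikes cluster within theta cycles, so the
effective sample size of a PPC estimate is closer to the cycle count than
the spike count; generator-level checks therefore average across seeds.

## Behavior scoring

`discrimination_index` is `(novel - familiar) / total` exploration time.
`concatenate_visits` accumulates visits from the start (or end) of a
session until 5 s and *truncates* the final visit at the threshold —
"until the accumulated time reached five seconds" reads as stopping at
the threshold; `truncate = FALSE` keeps the last visit whole for anyone
preferring the other reading. Sessions with less than 5 s return
everything with a `short` flag. `split_early_late` contrasts the first
and last 5 s of accumulated familiarization exploration, objects pooled,
and requires the 10-s validity minimum, which also guarantees the
partitions are disjoint. `passes_di_screen` implements the baseline
DI > 0.2 inclusion rule with a configurable cutoff.

## Auditory analysis

`epoch_trials` cuts per-trial snippets and subtracts each trial's mean
pre-stimulus baseline. `detect_aep` calls a trial responsive when its
peak absolute amplitude in 10-350 ms exceeds 3 x the SD of its own 500-ms
baseline; the criterion, window, and multiplier are configuration (no
published rule exists), and the 10-350 ms default brackets the P2
(40-70 ms) and P3 (200-300 ms) components. `component_metrics` reports
baseline-to-peak amplitude of the trial-averaged waveform within the
component window — a convention choice, documented as such — and the mean
multi-unit rate in 10-ms bins within the window. `mmn_analysis` enforces
frequency-matched flip-flop comparisons: each physical tone frequency's
deviant trials are compared only against the *same frequency* serving as
standard in the other block, never across frequencies; the difference
wave (deviant minus standard) is integrated over 40-200 ms (configurable;
no published window exists) to give the AUC in microvolt-milliseconds.

## Numerical choices and degenerate inputs

* Zero-phase filtering throughout (forward-backward IIR, or linear-phase
  FIR with integer delay compensation); any phase distortion would bias
  every phase-based statistic.
* The analytic signal is the standard FFT construction.
* MI errors on an all-zero envelope; PPC requires two phases; the DI
  requires a visit to each object class; PSI requires at least two
  frequency bins in the band and falls back to a single full-length epoch
  (with a warning) on short records.
* Ties and truncation in visit concatenation resolve toward exactness:
  the accumulated time equals `min(target, available)` exactly.
* All epoch conventions are half-open `[start, end)` in seconds.
* Generators draw all randomness from one seed; identical seeds give
  bit-identical sessions. The DPSS inverse iteration uses a deterministic
  start vector so taper computation never perturbs the user's RNG stream.

## Problem sizes used in validation

The test suites run at desk scale, with sizes chosen to keep each check's
sampling error well inside its tolerance: 30-120 s of
synthetic LFP at 1 kHz for coupling and connectivity checks, 20 seeds for
sign-recovery rates, 40 seeds x 240 s at 200 Hz for the PSI type-I
calibration with 200-shuffle surrogates (the full 1000 is the analysis
default), 20 click sessions of 100 trials for the response-ratio
recovery, and 20 oddball sessions of 400 trials for MMN sign recovery.

## Known limitations

* PSI on oscillations much narrower than the analysis band loses
  sensitivity (few coherent frequency bins carry the slope).
* The comodulogram's fixed 10 Hz amplitude bandwidth attenuates coupling
  whose sidebands fall outside the band (see above); interpret on-grid MI
  magnitudes comparatively, not absolutely.
* The AEP detector's false-alarm rate depends strongly on the background
  autocorrelation; against broadband noise a fixed 3-SD peak rule is
  liberal by construction.
* Group-level statistics (paired t-tests, repeated-measures and mixed
  ANOVA, post hoc corrections, correlations) are deliberately left to
  standard tools (`stats`, `car`, `emmeans`); the package produces the
  per-session quantities those models consume.
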