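---
title: "The oculomotor generative model and its analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The oculomotor generative model and its analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

oculoscope treats posterior EEG phenomena as consequences of oculomotor
action. Three ingredients generate a trial:

1. **A pre-saccadic kernel.** Every saccade is preceded by a fixed
   biphasic waveform: a positive Gaussian bump (P1-like) followed, 80 ms
   later, by a deeper negative Gaussian trough (N170-like); the trough
   sits 120 ms before saccade onset. Trial EEG is the exact linear
   superposition of one kernel copy per saccade.
2. **Fixation-control events.** Holding gaze on a target is modelled as
   an active process: small corrective signals recur with inter-event
   intervals drawn from a truncated normal with mean 105 ms during the
   pre-stimulus fixation interval. Each event contributes a small
   biphasic, *zero-net-area* deflection.
3. **1/f background noise**, generated by spectral shaping of white
   noise (power ∝ 1/f, sd 2 a.u.), independent across trials.

Event timing: the first saccade after stimulus onset has a truncated
normal latency (mean 290 ms, sd 25 ms, bounds 150–450 ms); subsequent
exploratory saccades form a renewal train (intervals truncated-normal,
mean 300 ms, bounds 120–800 ms) whose rate is multiplied by a
condition-specific `rate_scale` (1.0 for high exploration, 0.6 for low)
and decays exponentially over viewing time (taper 0.5 s⁻¹).

No oscillatory source and no "cognitive" component exist anywhere in
the generator. The phenomena the analysis chain recovers — a
stimulus-locked P1–N170-like complex near 170 ms, a sustained LPP-like
positivity that scales with exploration rate, saccade-locked troughs
converging 120 ms before saccade onset, and an 8–10 Hz fixation-interval
spectral peak — are all consequences of event timing statistics.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `p1_amp`, `n170_amp` | +1.1, −1.5 | a.u. | trough deeper than peak, but peak *area* larger (below) |
| `p1_sigma`, `n170_sigma` | 0.030, 0.013 | s | peak-to-trough ≈ 100 ms complex width |
| `p1_to_trough` | 0.080 | s | separation of bump centres |
| `pre_saccade_lag` | 0.120 | s | trough leads saccade onset; inside the empirical 100–150 ms band |
| first-saccade latency | N(0.290, 0.025) on [0.15, 0.45] | s | stimulus-locked trough ≈ mean − lag = 170 ms |
| exploratory IEI | N(0.300, 0.080) on [0.12, 0.80] | s | 2–3 saccades/s early viewing |
| control IEI | N(0.105, 0.015) on [0.06, 0.20] | s | spectral mass at 1/IEI ≈ 9.5 Hz |
| control amplitude | 0.4 | a.u. | small relative to the saccadic kernel |
| noise | exponent 1.0, sd 2.0 | — / a.u. | aperiodic background of realistic size |
| sampling rate | 250 | Hz | matches the instrumentation being emulated |

Three of these defaults were genuinely open and deserve their rationale:

* **Kernel area.** The sustained post-stimulus component is, in
  expectation, the saccade-rate function convolved with the kernel, so
  its *sign* is the sign of the kernel's time-integral. A net-positive
  kernel (broader P1 lobe) is required for the high-minus-low difference
  to be a positive, LPP-like wave; a net-negative kernel would produce a
  sustained negativity. The defaults give area
  `A_P1·σ_P1 − |A_N170|·σ_N170 > 0` while keeping the trough the
  deepest point of the waveform.
* **Latency spread.** Convolving the kernel with the first-saccade
  latency density shifts the smeared trough later, by roughly
  (P1 slope at the trough)/(N170 curvature). With sd 40 ms that shift is
  15–25 ms; with sd 25 ms the stimulus-locked trough stays near
  mean − lag = 170 ms. We chose 25 ms from this closed-form analysis
  before running any acceptance measurement.
* **Control-event polarity.** A renewal train of deterministically
  sign-alternating impulses has its spectral mass at odd harmonics of
  `1/(2·IEI)` ≈ 4.8 Hz — not in the alpha band. Same-polarity events
  with a zero-net-area kernel put the peak at `1/IEI` ≈ 9.5 Hz, and the
  ERP still cancels: the kernel integrates to zero and each trial's
  train carries a random phase relative to the epoch clock. Deterministic
  alternation remains available (`control_polarity = "alternate"`).

## What the synthetic data emulate — and what they do not

Sessions (`generate_session`) emulate: jittered baseline fixation
(3 ± 0.5 s for the face preset) followed by stimulus viewing; posterior
channels (O1, O2, POz) carrying the oculomotor trace with per-channel
gains and other channels carrying independent noise; gaze as a
mean-reverting, low-passed fixational drift (sd 15 px) with smooth
~25 ms saccadic steps toward stimulus feature targets and a return step
at stimulus offset; blink-like loss gaps; pupil as a slow oscillation
plus noise.

They do **not** emulate: volume conduction or any head model (channels
are abstract gains), pursuit or vergence, microsaccade kinematics (main
sequence), tracker-specific artifacts beyond white measurement noise, or
non-stationary noise. A green test therefore establishes that the
*analysis chain* recovers the *modelled* oculomotor structure at
realistic SNR — not that real data contain that structure.

## Numerical choices

* **Windows are half-open** `[t0, t1)` everywhere; the 150–300 ms
  sorting window includes 150 and excludes 300. This makes density-map
  and epoch partitions additive.
* **TFR**: 0.5 s Hanning windows stepped 50 ms give the 2 Hz grid with
  no zero-padding. Segments are demeaned before tapering (a Hanning
  taper leaks DC into the 2 Hz bin). Window centres advance by
  `floor(step·fs)` sample patterns so that shifting a signal by a whole
  number of samples shifts the map by whole columns; edge windows are
  `NA`. "−Inf" in the dB baseline window means the earliest valid time
  point.
* **Aperiodic removal** is a deliberate simplification: least-squares
  `log10 P ~ a − b·log10 f` over 2–40 Hz excluding an 8–13 Hz notch; the
  residual is the periodic part. It is exact on pure 1/f input and
  recovers ≥90% of a planted Gaussian bump, which is all the pipeline
  needs from it.
* **Saccade detection** thresholds velocity at median + 6·MAD (minimum
  duration 12 ms, merge gap 20 ms). Onsets are corrected for the
  temporal support of the centred velocity estimator ((w−1)/2 + 1
  samples, propagated as an attribute of `eye_velocity` output);
  detection should run on a short (≈12 ms) smoothing window, while the
  100 ms window remains the default for velocity *time-courses*. At
  250 Hz, onset estimates are typically exact to one sample with a small
  early tail — which is why the distributional (KS) contract is tested
  on generator ground truth and detection is tested as recovery accuracy.
* **Stratification** keeps `min(n_a, n_b)` trials per common histogram
  bin (20 bins, seeded uniform subsampling). The post-selection mean
  difference of the stratified variable is bounded by one bin width;
  when the pre-difference exceeds that, stratification shrinks it.
* **Cluster permutation tests** form clusters at pointwise two-tailed
  p < 0.05 (t with the appropriate df), sum t within 4-connected
  components (1D runs on time-only lattices), and compare each cluster's
  |mass| against the permutation distribution of the maximal |mass|
  (sign flips when paired, label shuffles otherwise), with the +1
  correction. Channel neighbourhoods come from a spherical 10–20
  template with a 100 mm threshold.
* **Mixed models** delegate to lme4; reported p-values are Wald-z
  approximations of the t statistics (lme4 reports no denominator df).
  The 2×2 within-subject ANOVA is the per-subject contrast
  decomposition, `F = n·mean(c)²/var(c)` on (1, n−1) df, verified
  against `aov()` in the tests.
* **Reproducibility**: one master seed; per-trial and per-stream
  sub-seeds derived by a 31-bit counter mix (`derive_seed`), so any
  trial can be regenerated in isolation and runs are byte-identical.

## Known limitations

* The renewal structure of exploratory saccades makes the trial-averaged
  ERP *ring* at ~1/IEI after the first saccade; fixed LPP windows
  therefore alias some of that ringing, and sustained-component
  comparisons are best made on windows spanning the whole viewing period.
* At the default noise level (sd 2 a.u.) the condition difference of the
  sustained component (~0.03–0.04 a.u.) needs several thousand trials
  per condition to clear the 1/f noise floor; mechanism-level tests run
  at reduced noise.
* The fixation-alpha elevation over the task interval is small in raw
  band power at default noise because exploratory kernels also carry
  some 8–12 Hz energy; the dissociation is unambiguous at low noise and
  in the aperiodic-removed fixation spectrum.
* p-value resolution of permutation procedures is `1/(n_perm + 1)`;
  500 permutations cannot produce p < 0.002.
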