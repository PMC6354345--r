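---
title: "Methods: EEG analysis for a mental-imagery BCI"
author: "lockbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG analysis for a mental-imagery BCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lockbci` implements the complete analysis chain used to assess and operate
an endogenous (stimulus-free) brain-computer interface from multichannel
EEG: an auditory-oddball ERP assessment of hearing and cognition, an
event-related spectral perturbation (ERSP) characterization of
mental-imagery tasks, two classification frameworks for single-trial task
decoding, and the evaluation protocols around them. The package targets the
situation where such analyses matter most — patients in a completely
locked-in state (CLIS), who cannot produce any voluntary movement and for
whom imagery-driven EEG decoding may be the only communication channel.
Because clinical recordings of this kind are rarely shareable, a seeded
synthetic-EEG generator reproduces the statistical structure the analyses
assume, so every stage is testable end to end.

## Paradigms and preprocessing

Two session types are modelled.

**Auditory oddball.** Each trial presents three standard noise bursts and
two deviant beeps (high- and low-pitch, one attended) of 80 ms each, with
inter-stimulus intervals drawn uniformly from 480-600 ms; 20 trials per run,
6 runs. The analysis chain is: common average reference (CAR), per-channel
DC removal, 1-30 Hz third-order Butterworth applied forward and backward
(zero phase), epochs from -100 to 1000 ms, baseline correction by the
pre-stimulus mean, and a +-75 uV amplitude screen.

**Mental imagery.** Trials present a variable 3-8 s rest, a 6 s auditory
cue, then a 5 s task period in which the subject performs left-hand motor
imagery (LMI), tongue motor imagery (TMI) or mental subtraction (MS); runs
are counter-balanced. The chain is CAR, DC removal, 4-45 Hz fifth-order
zero-phase Butterworth, 0-5 s task epochs, and downsampling to 512 Hz
through an order-8 Chebyshev-I anti-alias low-pass at 0.8x the new Nyquist
(0.02 dB design ripple; the forward-backward pass doubles the ripple, so
in-band droop stays below 1%).

Conventions fixed once and used everywhere: sample indexing is 0-based with
half-open windows and `floor(time * rate)`; filters run on the continuous
recording before epoching, with odd-symmetric padding of three filter
lengths at the recording edges. Both chains are exposed as configured
`preproc_pipeline()` objects that serialize to JSON and replay
bit-identically.

## Oddball ERP statistics

Condition averages are plain arithmetic means. The mismatch negativity
(MMN) is characterized per channel as the minimum of the deviant-minus-
standard difference waveform within 100-300 ms (earliest-latency
tie-break). Standards are subsampled (seeded, order-preserving) to match
the deviant count. Significance uses a moving window of 62.5 ms with 50%
overlap across the analysis span; each trial's mean amplitude per window is
the paired observation, tested with a two-sided paired t-test per channel
and window, Bonferroni-corrected over the full family (channels x
windows — the most conservative defensible family). Trials are paired by
position after subsampling. Degenerate windows are defined explicitly:
identical pairs give t = 0; a constant non-zero difference gives an
infinite t (perfectly consistent effect).

## ERSP

Time-frequency maps use Morlet wavelets on a 1 Hz grid (default 4-45 Hz),
with `3 + 0.75 * (f - f_min)` cycles at frequency `f`. The linear cycle
growth keeps the spectral bandwidth near-constant at ~1.3 Hz, matched to
the grid, so a band-limited power change reads out at its true dB value
instead of bleeding into neighbouring bands; the cost is ~0.1-0.2 s of
temporal smoothing, irrelevant for 5 s task windows. Power is averaged
over trials and expressed as `10 log10(P / P_baseline)` against the -1..0 s
pre-task mean. Band topographies average the map over a band and the 0-5 s
task interval. Band definitions follow the time-frequency analysis
convention (theta 4-7, alpha 8-13, low-beta 13-20 Hz) and are arguments
everywhere; the classification module uses its own convention (low-beta
14-20 Hz). No significance masking is applied to ERSP maps.

## Riemannian-geometry classification

Each trial's spatial covariance matrix (SCM) is `P_i = X_i X_i' / (N_t - 1)`
on the filtered, mean-free 5 s epoch. SCMs are symmetric positive-definite
(SPD) and are compared with the affine-invariant Riemannian distance
`d(P1, P2) = sqrt(sum_i log^2 lambda_i)`, `lambda_i` the generalized
eigenvalues of the pair. The Riemannian (Karcher) mean minimizes the summed
squared distances and is computed by fixed-point iteration in the tangent
space: initialized at the arithmetic mean, iterating
`M <- M^1/2 exp(mean_m log(M^-1/2 P_m M^-1/2)) M^1/2` until the tangent-mean
Frobenius norm falls below 1e-9 (cap 50 iterations; the step is halved when
the gradient norm increases — an objective-based line search was tried and
stalls once objective differences sink below numerical noise).

Trials map to the tangent space at the training-set mean,
`L_i = log(M^-1/2 P_i M^-1/2)`, half-vectorized with sqrt(2) off-diagonal
weighting so the Euclidean norm equals the Riemannian distance from the
reference; 19 channels give S = 190 features. A one-way ANOVA screens
features at p < 0.05 (uncorrected; single-best fallback if none pass), and
a two-class LDA with pooled covariance classifies. When the pooled
covariance is ill-conditioned (condition number above 1e8) it is shrunk
toward its diagonal by the smallest amount restoring invertibility.

Numerical note: CAR leaves every SCM with an exact null direction (the
common-average vector), which pushes the eigendecompositions used by the
log/exp maps to their accuracy floor. SCMs are therefore conditioned with
an escalating diagonal ridge until the smallest eigenvalue exceeds 1e-5 of
the mean diagonal power (~0.001% of signal power). Weaker ridges leave the
mean iteration's attainable gradient norm above its tolerance; the shared
inflated direction contributes near-constant tangent coordinates that the
ANOVA screen discards.

## Band-power classification

The conventional framework computes, per trial, Hamming-windowed FFT
periodograms on nine 1 s segments (50% overlap), averages spectral power
over segments, then over the bins of five bands (theta 4-7, alpha 8-13,
low-beta 14-20, high-beta 21-30, gamma 31-45 Hz; inclusive bin edges,
shared bins assigned to the lower band; periodograms scaled by window
energy). This yields 95 features (19 electrodes x 5 bands,
electrode-major order) plus five inter-hemispheric asymmetry ratios
`(R - L) / (R + L)`, with hemispheres left = {O1, C3, T7, FC1, FC5, F3,
F7, AF3}, right = {O2, C4, T8, FC2, FC6, F4, F8, AF4}, midline excluded
(the map is configurable). Segment averaging precedes the ratio.

Feature subsets are chosen by sequential floating forward selection (SFFS)
with the leave-one-out 1-nearest-neighbour error on standardized features
as criterion, capped at 10 features; ties break to the lowest feature
index, making selection fully deterministic. Back-ends are the in-package
two-class LDA or a linear SVM (C = 1, features standardized by training
statistics). Within every cross-validation fold, standardization, SFFS and
the classifier are refit on the training trials only.

## Evaluation protocols

`loocv()` refits the complete pipeline — including the tangent reference
and feature selection — per fold; per-trial feature extraction (SCMs, band
powers) is computed once because it involves no other trials.
`pairwise_task_comparison()` scores all task pairs; `electrode_curve()`
averages LOOCV accuracy over channel subsets per montage size (exhaustive
when there are at most `max_subsets` combinations, seeded sampling
otherwise — the full 2^19 sweep is computationally absurd);
`online_simulation()` fits once on a training session and predicts test
trials in chronological order with per-run feedback accuracies;
`test_retest()` compares stale, fresh and combined training sets on one
test session. `chance_level()` provides both the Wald bound
`0.5 + z sqrt(0.25 / n)` and the exact binomial tail bound; the exact bound
dominates at small n. Every report embeds the pipeline configuration hash
and seed, and every CLI run writes a manifest from which
`replay_manifest()` reproduces all outputs bit-identically.

## The synthetic-EEG generator

The generator renders a paradigm schedule into a continuous recording:

* **Background**: independent per-channel 1/f noise (default exponent 1,
  10 uV RMS), synthesized by frequency-domain shaping of white noise (FFT
  lengths padded to 2-3-5-smooth sizes). No spatial correlation, no
  EOG/EMG artifacts, no volume conduction.
* **ERP components**: Gaussian pulses per condition (latency, width,
  amplitude, channel weights). Oddball defaults: MMN of -3 uV at 200 ms
  (width 30 ms) on Fz/FC1/FC2/Cz for both deviant beeps, plus a delayed
  P300 of +2.5 uV at 600 ms on Fz/Cz/T7/T8 for the attended target —
  the delayed-positivity pattern the assessment is designed to detect.
* **ERD/ERS signatures**: per condition, a frequency band, a channel set
  and a modulation fraction m. The channel's in-band component (ideal FFT
  band split) is scaled so in-band power is multiplied exactly by (1 + m)
  during the task window. A purely additive band-limited component cannot
  express desynchronization (m < 0), so each signature also carries a
  resting rhythm: the in-band component is raised by `rhythm_gain` (default
  1, i.e. the rhythm contributes as much in-band power as the 1/f floor at
  those channels) at all times — emulating the ongoing sensorimotor or
  frontal rhythms that tasks modulate — and the task scales the whole
  in-band component, keeping the task/rest ratio at exactly (1 + m).
  Imagery defaults at modulation 0.5: LMI = low-beta (14-20 Hz) ERD of
  -0.5 at C3/C4 with slight alpha ERS (+0.2) at C4; TMI = the same
  low-beta ERD at C3/C4; MS = theta ERS (+0.5) and alpha ERD (-0.3) at
  AF3/AF4.
* **Session drift**: samples are mixed by `W = I + drift * G`, G a seeded
  random symmetric matrix of unit Frobenius norm, so covariances undergo
  the congruence transform `W P W'` — the perturbation class against which
  the affine-invariant classifier should be partially robust, enabling a
  meaningful test-retest experiment (the stale-session experiments use
  drift 0.15).

All randomness flows from one integer seed through derived per-stream
seeds; global RNG state is saved and restored. Schedules follow the
protocol counts (oddball 6 x 20 trials with 3 noises + 2 beeps each —
a `noises_per_trial` knob reaches alternative standard counts; offline
imagery 10 x 6 over three tasks, training 10 x 4, test 4 x 10 with
balanced runs).

## Problem sizes used by the test suite

The statistical-validity suites run at reduced scale, chosen so the
properties under test are unconfounded and the suite completes in ordinary
desk time: family-wise error uses 1000 null oddball sessions of 10 trials
at 4 channels/128 Hz; the no-leakage check uses 200 fresh 24-trial null
sessions (4 channels, 128 Hz, shortened rest/cue) with shuffled labels.
Trial counts matter here: leave-one-out cross-validation is itself
pessimistically biased on null data (the held-out trial's class is
under-represented in training), by about -0.05 at 12 trials and -0.02 at
24 trials — the 24-trial size keeps that nuisance bias inside the
tolerance so the check isolates selection leakage, which would bias the
other way. Parameter-recovery experiments run at the full protocol scale
(19 channels, 20 + 20 trials) but synthesize at 512 Hz, the rate the
imagery chain downsamples to anyway.

## Known limitations

* The generator's channel independence makes trial covariances nearly
  diagonal, so the Riemannian framework can only exploit per-channel
  variance changes: a -50% band power change moves a channel's
  log-variance by ~0.14 (the band's share of broadband power), while the
  per-trial estimation noise of log-variance under a 1/f spectrum over 5 s
  is ~0.11. With ~3 informative channels and an ANOVA screen that admits
  roughly `0.05 * 190` noise features, tangent-space LDA reaches ~0.6-0.8
  LOOCV at these settings, *below* the band-power framework, which reads
  the modulated bands directly and saturates. On real EEG the ordering
  reverses: task modulations reshape cross-channel covariance (volume
  conduction, correlated sources), which is precisely the structure the
  covariance framework exploits and the band-power features ignore.
  Passing recovery tests here therefore validates the machinery, not the
  real-data superiority of either framework.
* ERSP dB readouts of hard-edged synthetic band modulations are diluted at
  the band edges by the wavelet bandwidth (about 0.5-1 dB for a 6 Hz-wide
  band); real ERD/ERS has soft spectral edges.
* The moving-window family and the trial pairing rule are conservative
  choices among defensible alternatives; both are configurable.
* The montage lacks CPz; analyses that conventionally include it operate
  on the channels present and warn about missing ones.
* No streaming/online acquisition: the online experiment is simulated
  trial-wise on recorded buffers, which is equivalent for a 5 s-epoch
  protocol with feedback after each trial.
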