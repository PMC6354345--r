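# lockbci

EEG analysis toolkit for endogenous, mental-imagery brain-computer
interfaces (BCIs), built for the hardest use case: binary communication
with patients in a completely locked-in state (CLIS), who have no voluntary
motor channel left. The package implements the complete analysis chain such
a study needs —

* **Auditory-oddball ERP assessment** of hearing and cognition: common
  average reference, zero-phase Butterworth filtering, epoching, baseline
  correction, ±75 µV artifact screening; mismatch negativity (MMN, the
  minimum of the deviant−standard difference in 100–300 ms) and delayed
  P300 characterization; moving-window (62.5 ms, 50 % overlap) paired
  t-tests with Bonferroni correction.
* **Event-related spectral perturbation (ERSP)**: Morlet-wavelet
  time–frequency maps in dB against a −1…0 s baseline, with band-averaged
  topographies (ERD/ERS readout per task).
* **Riemannian-geometry classification** of mental-imagery trials: spatial
  covariance matrices `P_i = X_i X_iᵀ/(N_t−1)`, the affine-invariant
  distance `δ(P₁,P₂) = √Σ log²λ_i`, the Riemannian (Karcher) mean
  `ϑ = argmin_P Σ δ²(P, P_m)`, tangent-space mapping to
  `S = N(N+1)/2 = 190` features for 19 channels, one-way ANOVA variable
  screening, and LDA.
* **Band-power classification**: five-band spectral powers from 1 s
  Hamming/FFT segments (9 per 5 s epoch), inter-hemispheric asymmetry
  ratios `(R−L)/(R+L)` (95 + 5 features), sequential floating forward
  selection with a leave-one-out 1-NN criterion capped at 10 features, and
  LDA or linear SVM back-ends.
* **Evaluation protocols**: leave-one-out cross-validation with per-fold
  refitting of reference and selection, task-pair comparisons,
  electrode-count curves, simulated online runs with per-run feedback
  accuracies, test–retest with stale/fresh/combined training sets, and
  binomial chance-level bounds.
* **A seeded synthetic-EEG generator** (1/f background, Gaussian ERP
  components, exact band-power modulations, congruence-transform session
  drift) that stands in for patient data, so every stage is testable
  without any recording.

## Worked example

```r
library(lockbci)

# A synthetic online-training session: 10 runs x 4 trials of left-hand
# motor imagery (LMI) vs mental subtraction (MS), 19-channel montage.
rec <- synth_imagery_session(
  seed = 42, session_kind = "imagery_train", task_set = c("LMI", "MS"),
  rate = 512)
rec
#> <eeg_recording: 19 ch x 359399 samples (702.0 s @ 512 Hz), 50 marker(s)>

ep <- apply_preproc(rec, preproc_pipeline("imagery"))$epochs
ep
#> <eeg_epochs: 40 trial(s) x 19 ch x 2560 samples, window [0, 5] s @ 512 Hz>
#>   LMI: 20, MS: 20

report <- loocv(ep, bci_pipeline("bandpower", "lda"))
report
#> <eval_report 'bandpower_lda': overall accuracy 92.5% (40 trials)>
#>   per-run: 100%, 100%, 100%, 75%, 100%, 100%, 100%, 100%, 75%, 75%

100 * chance_level(n_trials(ep), 0.99, "exact_binomial")
#> [1] 72.5
```

The LOOCV accuracy (92.5 % over 40 trials) is the fraction of held-out
trials whose task was decoded correctly, with feature selection and
classifier refit on the remaining 39 trials in every fold; it clears the
99 % binomial chance bound (72.5 % at n = 40), i.e. the decoded
communication is far better than guessing. The same interface drives the
covariance-geometry pipeline (`bci_pipeline("riemann")`), online
simulations (`online_simulation()`), and test–retest comparisons
(`test_retest()`).

The oddball assessment works the same way:

```r
rec <- synth_oddball_session(seed = 7, rate = 512)
odd <- apply_preproc(rec, preproc_pipeline("oddball"))
dev <- subset_epochs(odd$epochs, odd$epochs$labels != "noise")
std <- subsample_standards(
  subset_epochs(odd$epochs, odd$epochs$labels == "noise"),
  n_trials(dev), seed = 7)
dev$labels[] <- "deviant"; std$labels[] <- "standard"
mmn <- detect_mmn(condition_average(bind_epochs(dev, std)),
                  "deviant", "standard")
head(mmn[order(mmn$amplitude), ], 3)
#>    channel   latency amplitude
#> 9       Fz 0.2066406 -2.956752
#> 4       Cz 0.1988281 -2.524362
#> 11     FC2 0.1988281 -2.134288
```

A fronto-central negativity of ≈ −3 µV near 200 ms — the MMN signature of
intact auditory change detection.

A command-line interface wraps the same functions
(`system.file("cli", "lockbci.R", package = "lockbci")`) with subcommands
`simulate`, `erp`, `ersp`, `evaluate` and `chance`; every run writes a
manifest (configuration, seed, output checksums) and `replay_manifest()`
re-executes it and verifies bit-identical outputs.

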