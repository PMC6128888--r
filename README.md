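# acusleep

Non-contact macro sleep staging from a night of audio.

`acusleep` estimates, for every standard 30-second epoch of a night, the
macro sleep stage — wake (W), REM (R) or NREM (N) — from a single
microphone channel (PCM WAV, mono, 44.1 kHz), and derives the standard
sleep-quality report from the resulting hypnogram. It is aimed at sleep
researchers and engineers who work on contactless sleep monitoring:
everything needed to train, run and evaluate the system on simulated
ground truth is in the package, since polysomnography-annotated audio of
real patients is generally not shareable.

## The method

The audible contrasts between stages drive the whole design: sleep
amplifies breathing sounds (higher upper-airway resistance), NREM
breathing is slow and metronomic, REM breathing is faster and irregular
while REM atonia suppresses movement sounds, and wake is movement-rich
with faint sparse breathing.

The pipeline: 50 ms frames (2205 samples) → adaptive
spectral-subtraction enhancement with the noise spectrum re-estimated
every 30 s epoch (gain `G² = max(1 − αN²/P, g_f²)`) → a four-class
frame detector emitting likelihood curves for inhalation, exhalation,
body movement and other sounds → a 67-feature epoch vector
**X**(:, *t*) in five families (within-breathing 33, between-breathing
12, body movement 10, background noise 8, personalization 4) → cascaded
classifiers. The real-time cascade C⁽ʳ⁾(**X**, *t*) declares epochs 1–5
wake and otherwise selects, by the epoch index *t*, one of five
single-hidden-layer tanh/softmax networks (hidden units
100/400/1000/1000/1000) fed the concatenated features of the current
epoch and its 5/20/50/100/200 predecessors. The offline cascade
C⁽ᵒ⁾(C⁽ʳ⁾, *t*) runs backward over the completed night's real-time
score triplets with the same window lengths (hidden units
20/50/100/200/200), keeping real-time scores for the final epochs
(T − 5 ≤ t). The final hypnogram yields eight report parameters: TST,
SL, SE, WASO, RL, RP, NP and the REM-cycle count. Agreement against a
reference is measured epoch by epoch (confusion matrices, accuracy,
Cohen's κ, 2-class sleep/wake collapse) and per parameter (Lin's
concordance correlation, Bland–Altman limits).

A seeded night simulator provides ground truth end to end: semi-Markov
hypnograms (sleep latency ~15 min, ~95-min NREM/REM cycles, brief
awakenings), stage-conditioned audio (band-limited breath bursts at
15 dB SNR over a −45 dBFS stationary background, movement bursts,
third-party transients) and exact frame-level event labels.

## Worked example

Simulate a short night, train the two model stages on simulated nights,
and stage a held-out night:

```r
library(acusleep)

# same protocol (and seeds) as scripts/acceptance.R with --seed 1:
# 2-hour (240-epoch) simulated nights, 16 for training, 4 held out
cfg <- acusleep_config_reduced(seed = 1)
night_cfg <- function(i) acusleep_config(
  seed = (131 + 7 * i) %% 2147483647,
  simulator = list(night_epochs = 240))

# 1. frame detector, trained on labeled frames from simulated nights
det_nights <- lapply(1:5, function(i) simulate_night(night_cfg(i), materialize = FALSE))
det <- train_detector(
  collect_detector_frames(det_nights, cfg, epochs_per_night = 20), cfg)
det
#> <event_detector> classes: inhale/exhale/body_movement/other |
#>   18018 training frames | held-out accuracy 0.969

# 2. staging cascades, trained on per-night features
nights <- lapply(1:16, function(i) {
  n <- simulate_night(night_cfg(i), materialize = FALSE)
  list(features = extract_night_features(n, det, config = cfg),
       hypnogram = n$hypnogram)
})
casc <- train_cascades(nights, cfg)

# 3. stage the held-out nights and read one report
staged <- lapply(17:20, function(i) {
  night <- simulate_night(night_cfg(i), materialize = FALSE)
  sn <- stage_night(night, det, casc, config = cfg)
  list(sn = sn, truth = night$hypnogram)
})
staged[[1]]$sn$report
#> Sleep quality report
#>   TST   104.0 min   SL      6.0 min   SE    86.7 %
#>   WASO    1.5 min   RL     82.0 min   RC   1 cycles
#>   REM   19.7 %     NREM  80.3 %

# epoch-by-epoch agreement with the simulated truth
cms <- lapply(staged, function(x)
  confusion_matrix(x$truth, x$sn$scores$off_label))
round(vapply(cms, accuracy, numeric(1)), 1)
#> [1] 85.4 83.8 92.1 73.3
pooled <- Reduce(`+`, cms)
c(pooled_accuracy = accuracy(pooled), pooled_kappa = cohens_kappa(pooled))
#> pooled_accuracy    pooled_kappa
#>      83.6458333       0.6744533
```

The run takes about ten minutes on one CPU; the numbers are from one
seeded run of exactly this code, and the pooled accuracy equals the
`heldout_offline_accuracy_pct` the acceptance script writes for seed 1.
Per-epoch output (the `scores` tibble) carries both passes:
probabilities `rt_pW/rt_pR/rt_pN` and `off_*` plus hard labels.
`autoplot()` methods draw
hypnograms, probability curves and staged nights; `tidy()`/`glance()`
summarize fitted detectors, cascades and reports. A thin command-line
front end with `simulate`, `train`, `stage` and `evaluate` subcommands
is installed under `inst/cli/acusleep`.

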