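---
title: "Audio-based macro sleep staging: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audio-based macro sleep staging: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(acusleep)
```

## The estimation problem

`acusleep` estimates macro sleep stages — wake (W), REM sleep (R) and
NREM sleep (N) — for every standard 30-second epoch of a night, from a
single non-contact microphone channel (PCM, 44.1 kHz, 16-bit, mono). The
physiological premise is that the three states differ audibly: during
sleep, reduced pharyngeal dilator muscle activity raises upper-airway
resistance, which amplifies breathing sounds; NREM breathing is slow and
metronomic while REM breathing is faster and irregular; skeletal muscle
atonia makes REM essentially movement-free, whereas wake is dominated by
movement sounds and sparse, faint breathing. The pipeline turns those
contrasts into per-epoch features and classifies the feature time series
with two cascaded classifiers: a strictly causal real-time pass and an
offline pass that revisits the night with future context.

The full chain is:

1. **Framing** — the stream is cut into contiguous, non-overlapping 50 ms
   frames (2205 samples); 600 frames form one 30 s epoch. Trailing
   partial frames and epochs are discarded rather than padded, so no
   fabricated audio reaches the features.
2. **Noise suppression** — an adaptive spectral-subtraction gain in the
   Wiener family, with the background spectrum re-estimated once per
   epoch from the epoch's quietest frames.
3. **Event detection** — a shallow softmax network labels every frame
   with four likelihoods: inhalation, exhalation, body movement, other
   sounds.
4. **Feature extraction** — 67 per-epoch features in five families
   (33 within-breathing, 12 between-breathing, 10 body-movement,
   8 background-noise, 4 personalization).
5. **Staging** — the real-time cascade, then the offline cascade over the
   real-time scores.
6. **Reporting** — eight sleep-quality parameters from the final
   hypnogram, plus agreement statistics against a reference.

## Signal enhancement

Frames are analyzed through a single Hann window centered in the frame
(`enhancement$window`, default 512 samples, i.e. 86 Hz resolution). One
window per frame is a deliberate choice: frames are 50 ms and the sounds
of interest are broadband and noise-like, so one centered window
estimates the frame spectrum adequately at a fraction of the cost of
dense multi-window transforms, which matters when a full night is half a
gigabyte of samples per hour.

The background-noise profile is the root-mean power spectrum of the
lowest-energy `noise_quantile` (default 20%) of each epoch's frames,
blended exponentially with the previous profile. The blend is
asymmetric per bin — weight 0.9 on the past when the level falls,
0.7 when it rises — the usual behavior for background trackers: a fan
switching on is followed within a few epochs, while a quiet spell does
not erase the profile; sound events cannot leak in because the
low-energy quantile excludes them. Tracking is strictly causal — only
current and past epochs contribute — so the real-time guarantee holds
end to end. The per-bin gain is

  G^2 = max(1 − α·N²/P, g_f²)

with over-subtraction α (`oversubtraction`, default 3) and a spectral
floor `floor_db` (default −25 dB). With α = 3, frames containing only
the tracked noise lose more than 10 dB while a transient only 20 dB
above the floor loses well under 1 dB — stationary hums are removed,
impulsive third-party noises survive for the event detector to classify.
Reconstruction (`enhance_frame()`) applies the gain on the full
2205-point spectrum with phase preserved.

Because absolute calibration is out of scope, amplitudes are normalized
to full scale ±1 on read and every intensity in the package is dB
relative to full scale (dBFS), floored at −80 dBFS (−100 dB for log
energies of digital silence).

## Event detection

One four-class network replaces a pair of parallel binary detectors: the
outputs are identical in form (four normalized likelihood curves at
50 ms resolution) and a single softmax enforces normalization. Each
frame is described by 17 acoustic features (log energy, normalized
spectral entropy, centroid, 95% roll-off, zero-crossing rate, four
band-energy ratios over 50–300/300–1000/1000–2000/2000–8000 Hz, and
cepstral coefficients 1–8 from 24 log-spaced bands). Features are
z-scored with training-set statistics stored in the model. Digitally
silent frames map to a defined vector (energy at floor, entropy 1,
everything else 0) and are forced to the "other" class. The classifier
is a single-hidden-layer network (tanh hidden layer, 16 units by
default) trained with inverse-class-frequency weights, full-batch Adam
and early stopping on a held-out fraction; all randomness derives from
the configuration seed.

Breathing periodicity is summarized by the autocorrelation of the
mean-removed inhalation curve. Per-lag estimates use the unbiased
1/(n−k) scaling so an exactly periodic curve scores 1 at its period; the
first positive local maximum (strictly greater than its ±2 neighbors,
to ignore single-lag ripple) in the physiologic lag band 1–10 s
(breathing rates 6–60 per minute) is the reported peak. Bounding the
band matters at the sparse end: an isolated pair of wake breaths twelve
seconds apart is not breathing periodicity, but unbiased scaling would
happily score it as one. A zero-variance curve returns a missing peak
with a flag rather than a number.

## The 67-feature registry

The five families and their counts are fixed; the exact member list is
this package's reconstruction, documented in `feature_registry()` and
frozen under a registry hash that every trained cascade records — a
cascade can never silently consume features in a different order.
Statistics that are undefined for an epoch (duration moments with no
events, intervals with fewer than two breaths) carry the sentinel −999
until model-fit time, when they are replaced by training-set medians:
classifier inputs stay finite without biasing toward any class. Features
of epoch *t* use only epochs ≤ *t*; the two history-bearing features
(noise-floor delta, transient rate over the trailing five epochs) look
strictly backward.

## The staging cascades

The real-time classifier is six sub-classifiers selected by the epoch
index: epochs 1–5 are declared Wake outright (recordings start at
lights-off, when subjects are awake); epochs 6–20, 21–50, 51–100,
101–200 and beyond 200 use networks with 100/400/1000/1000/1000 hidden
units fed the raw concatenation of the feature vectors of the current
epoch and its 5/20/50/100/200 predecessors. The offline classifier runs
backward over the completed night's real-time score triplets with
lookahead windows of the same lengths and 20/50/100/200/200 hidden
units; epochs with T − 5 ≤ t keep their real-time scores. (The defining
inequality covers six epochs, one more than the accompanying "five last
epochs" phrasing; the package follows the inequality, which the
structure self-test asserts.) Sub-classifiers are single-hidden-layer
tanh/softmax networks; the optimizer (Adam, learning rate 0.05, ≤ 200
iterations, patience 20, L2 5×10⁻⁴) is a configuration value.

Design choices worth calling out:

* **Windows include the current epoch**, so period-2 inputs have length
  67 × 6 = 402 and period-6 inputs 67 × 201 = 13,467.
* **Period selection degrades gracefully for short nights**: the offline
  period of epoch *t* is the smallest period whose window reaches *t*,
  which reproduces the defining inequalities exactly for long nights and
  keeps every window in range for short ones.
* **Single-class periods**: if every training epoch of one period has
  the same label (a corpus where nobody slept before epoch 20, say),
  that period's sub-classifier degenerates to a constant emitting that
  class — a fit, not an error. A stage missing from the corpus entirely
  *is* an error.
* **Subject-level splitting**: the 80/20 train/development split is by
  night, never by epoch, so development loss measures generalization to
  unseen subjects; development loss drives early stopping.
* **Class imbalance** (NREM is roughly 70% of epochs) is handled by
  inverse-frequency loss weights.
* **Ties** in the final argmax resolve by the fixed priority N > R > W.
* `train_cascades()` refuses corpora whose nights are too short to
  train a period (naming the period); `allow_missing_periods = TRUE`
  permits training anyway, with untrained periods falling back to the
  largest trained shorter window at inference.

The full-width cascade is sized for a training corpus of hundreds of
patient-nights. `acusleep_config_reduced()` keeps every boundary and
window but thins the hidden layers (4/8/16/16/16 real-time,
4/8/10/16/16 offline); it is the profile used by the package's test
suite and acceptance script, where the design corpus is 16–40 simulated
nights.

## The sleep report

Eight parameters from the final hypnogram: TST (minutes scored R or N),
SL (recording start to first non-wake epoch; recordings are assumed to
start at lights-off), SE (100·TST/recording time), WASO (wake between
sleep onset and the final awakening — trailing wake is excluded), RL
(start to first R epoch; missing if no REM), RP and NP (percentages of
TST), and the REM-cycle count. REM cycles are maximal runs of R merged
when separated by fewer than `rem_gap_epochs` (default 60 epochs =
30 min) non-R epochs, discarding merged clusters with fewer than
`rem_min_epochs` (default 2) R epochs. The merge gap and minimum size
are configuration values; the defaults give realistic 0–4 cycle counts
on simulated nights. The stated definitions of RP/NP use TST as the
denominator; published summary tables in this literature sometimes imply
a time-in-bed denominator instead, so a config switch
(`report$percent_denominator`) preserves both, with the stated
definition as default. An exact conservation identity holds whenever any
sleep occurred: SL + WASO + TST + trailing wake = recording length.

## The night simulator

Patient recordings are not distributable, so the simulator is the
package's source of ground truth, and it is first-class, tested code.
The hypnogram generator is semi-Markov: an initial wake bout
(N(15, 5) min, floored at 3 min so epochs 1–5 are always wake),
alternating NREM/REM bouts with cycle period N(95, 10) min and REM bouts
N(18, 5) min, brief awakenings (1.5/h, ~3 min) carved out of NREM so
REM-onset spacing is preserved, and an optional terminal wake bout.

Audio synthesis is stage-conditioned: NREM breathes at 14 breaths/min
with 5% interval jitter; REM at 16 breaths/min (SD 2 across epochs) with
25% jitter and no body movement; wake has sparse, 8 dB-attenuated
breaths (40% jitter) and frequent broadband movement bursts
(1.5/epoch; NREM 0.1; REM 0). Inhales (1.0 ± 0.15 s) and exhales
(0.8 ± 0.15 s) are band-limited noise bursts (300–2000 Hz and
200–1000 Hz) — overlapping but separable bands, so detection is
non-trivial; movement is broadband 100–8000 Hz; Poisson third-party
transients (0.3/min, 0.2–0.4 s) occur in every stage. Events are scaled
so that mean power over the event sits at the configured SNR (15 dB)
above the stationary background (−45 dBFS, mildly low-passed white
noise). Every event's frames are recorded as ground-truth labels
(movement takes priority over breathing where they overlap).

One night-level seed fixes everything. Because a materialized 7-hour
night is ~9 GB of doubles, `simulate_night()` also works lazily: the
night stores its event schedule and templates (~60 MB) and reconstructs
any epoch's audio deterministically on demand; lazy and materialized
audio are bit-identical, which the tests assert. Longer-than-epoch
structure in the background (the same shifted noise template reused
across epochs) is a known simplification.

What the simulator does *not* emulate: realistic snore spectra and their
inter-subject variability, apnea events, room reverberation, position-
dependent level changes, or recording-device coloration. Passing the
package's tests therefore demonstrates that the pipeline recovers stage
structure when the assumed acoustic contrasts exist at the configured
SNR; it does not certify clinical performance on real patients.

## Numerical choices and degenerate inputs

* FFT-based autocorrelation with unbiased per-lag scaling, clipped to
  [−1, 1]; periodograms of the inhalation curve are zero-padded to 2048
  points (0.01 Hz resolution around breathing rates).
* Detected events are maximal runs of argmax frames with probability
  ≥ 0.5 and length ≥ 3 frames (150 ms); shorter runs are detector noise.
* "Other sound" events must additionally exceed the epoch's noise floor
  by 6 dB, so background frames do not count as transients.
* All-zero audio propagates cleanly: zero profile, zero enhanced output,
  "other" curves, finite (sentinel/floor) features.
* Training is full-batch, so fits are bit-reproducible from the seed on
  a given BLAS.

## Scale of the packaged experiments

The test suite and `scripts/acceptance.R` run the whole system at a
desk scale chosen to exercise every cascade period while staying
tractable: the recovery study in the test suite simulates 50 nights of
300 epochs (2.5 h) with the reduced profile, training on 40 and testing
on 10; the acceptance script runs 20 nights of 240 epochs (16/4).
Nights are simulated, consumed and discarded one at a time so peak
memory stays modest. The full-width, full-night configuration is the
package default for real use.

## Known limitations

* The 67-feature registry is a reconstruction: the family structure and
  counts follow the published description, but individual members are
  this package's choices and are therefore configurable in order.
* The frame-level detector is a generic shallow classifier, not a
  re-implementation of any particular published snore detector.
* Sleep-stage scoring below the W/R/N level (NREM sub-stages) is out of
  scope, as is apnea detection.
* Real-time here means algorithmic causality, not an audio-capture
  runtime.
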