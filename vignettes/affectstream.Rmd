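---
title: "Streaming EEG affect classification: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming EEG affect classification: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectstream)
```

## The problem

Affective states are commonly summarized by two dimensions of the
circumplex model: *valence* (unpleasant to pleasant) and *arousal*
(sleepy to excited). When EEG is recorded by a consumer wearable while a
person watches emotion-eliciting videos, two things distinguish the
setting from classic offline EEG classification:

* samples arrive as a *stream*, so the classifier must learn
  incrementally, one feature vector at a time; and
* the ground-truth rating for a stimulus exists only *after* the
  stimulus ends, so labels arrive with a delay of up to the stimulus
  length.

`affectstream` implements the full chain — device profiles and stream
replay, per-window preprocessing, band-power features, interval-based
label matching, incremental classifiers, and both immediate and delayed
prequential evaluation — together with a synthetic session generator
that makes every stage testable with known ground truth.

## Windowing

EEG is treated as stationary only over short intervals, so all
processing happens in *tumbling* (fixed-length, non-overlapping)
windows of `l × sf` samples, where `sf` comes from the device profile,
never from timestamp spacing. Windows are half-open intervals
`[t, t + l)`. When windows can be placed freely relative to a stimulus
they are tiled backward from the stimulus end, giving
`floor(duration / l)` windows per stimulus; when pre-existing windows
must be used, only windows lying wholly inside the stimulus interval
count. The default window length is 1 s; `run_window_sweep()` exposes
the 1–5 s sweep.

In the immediate-label setting, labeled windows are *shuffled* (with
their labels) before the prequential pass. Long runs of identical
labels — every window of a 90 s video shares one rating — otherwise let
a stream learner coast on label persistence instead of learning from
features. Shuffling needs the whole labeled block, so it is only
possible on recorded data, never live; the delayed protocol therefore
runs unshuffled, which is part of why delayed results are worse.

## Preprocessing

Each window is cleaned independently — no filter state crosses a window
boundary, which keeps windows exchangeable for shuffling and keeps the
stream pipeline stateless:

1. a second-order IIR notch (biquad with unity passband gain and a zero
   at the mains frequency, default 50 Hz, configurable to 60 Hz);
2. a fifth-order Butterworth band-pass from 0.5 to 45 Hz;
3. common average referencing (CAR): the instantaneous mean across
   channels is subtracted from every channel, *after* filtering.

Two numerical choices deserve explanation.

**Zero-phase filtering within the window is the default.** A filter
applied causally from the first sample of each window spends a large
part of a short window in its start-up transient: a second-order 50 Hz
notch narrow enough to spare the gamma band (which extends to 45 Hz)
leaves roughly a third of a pure 50 Hz tone's RMS in a 1-s window, not
because its steady-state response is poor (it is exactly zero at 50 Hz)
but because of the transient. Since features are only ever computed
from *complete, buffered* windows, running the filter forward and
backward inside the window is realizable in a live pipeline and removes
both the phase distortion and most of the transient. Forward-only
causal filtering remains available (`zero_phase = FALSE`).

**The notch quality factor defaults to q = 5.** The -3 dB bandwidth of
the notch is `f0 / q`. The operating point must balance two pressures:
settle within one second (favoring small q) and leave the upper gamma
band intact (favoring large q). At q = 5 with zero-phase filtering, a
steady 50 Hz tone in a 1-s window at 256 Hz retains under a tenth of
its RMS while the response at 10 Hz is above 0.999; the attenuation at
44 Hz (about 0.9) shaves only the extreme top of gamma. Both q and f0
are configurable via `preprocess_config()`.

CAR requires at least two channels and is exactly idempotent; its
assumption — an even potential distribution over the scalp — is taken
from standard practice for low-density montages.

## Feature schema

Per channel and window, the one-sided Welch power spectral density is
integrated over five bands — Delta 0.5–4, Theta 4–8, Alpha 8–16, Beta
16–32, Gamma 32–45 Hz — plus the total 0.5–45 Hz power, and the ten
unordered pairwise band ratios are appended: 16 features per channel,
so 64, 128 and 224 features for the 4-, 8- and 14-channel profiles. The
Alpha band's 16 Hz upper edge is wider than the textbook definition; it
is kept as stated because it is part of the feature-vector contract.
The ratio count fixes its orientation: only unordered pairs `i < j` in
the fixed band order (`delta/theta, delta/alpha, …, beta/gamma`) give
exactly `choose(5, 2) = 10`.

Welch parameters: segments of one second (so a 1-s window degenerates
to a single full-length segment — the primary setting), 50% overlap, a
periodic Hann taper, per-segment mean removal, density scaling. The
implementation is in-package (no installed R package provides a Welch
estimator) and is pinned in the test suite against frozen reference
values computed with an independent spectral-estimation implementation
on closed-form signals.

Band integration is a rectangle (Riemann) sum of the PSD over the
frequency bins whose centers fall in the half-open band `[low, high)`.
With trapezoidal integration over each band's selected bins, the
inter-band gap intervals would belong to no band and the five bands
would sum to visibly less than the total power; the rectangle rule
makes the five bands partition the 0.5–45 Hz range *exactly*, which is
asserted as an invariant. Ratio denominators carry an epsilon guard
(`1e-12`) for silent channels; no log transform is applied. Amplitude
scaling of the signal by `a` multiplies all powers by `a²` and leaves
all ten ratios unchanged — a property test.

## Labels

Ratings arrive as tuples `(dimension, rating, t_start, t_end)` with the
rating on the unit scale. A 9-point pictorial scale (as used by some
public datasets) is first mapped affinely by `(raw - 1) / 8`, which
puts the scale midpoint 5 exactly on the class boundary — a declared
convention chosen so a single thresholding code path serves both
scales. Binarization thresholds at 0.5 with ties going *high*
(configurable). A window receives a tuple's label iff it lies wholly
inside the tuple's interval; windows straddling stimulus boundaries
stay unlabeled, dimensions are independent, and overlapping tuples
within one dimension are rejected as ambiguous ground truth.

## Classifiers

All learners satisfy one contract: `predict_one(clf, x)` returns the
class and `P(high)` without mutating state; `learn_one(clf, x, y)`
performs one incremental update. Before any training every classifier
answers *high* with score 0.5, consistent with the tie rule, and such
predictions are scored like any other.

* **Online logistic regression** (`kind = "lr"`): single-sample SGD on
  the log-loss, learning rate 0.1, no regularization. Because raw band
  powers span orders of magnitude, the classifier wrapper keeps running
  per-feature means and variances and standardizes inputs online
  (`standardize = TRUE` by default; the exported primitives
  `lr_predict_one()` / `lr_learn_one()` are the bare update rules).
* **Adaptive random forest** (`kind = "arf"`): an online-bagging
  ensemble of incremental Hoeffding trees. Each tree weights each
  example by a Poisson(6) draw; each leaf considers a random subset of
  `ceiling(sqrt(d))` features; each tree carries an error-rate drift
  detector (the classic `p + s` vs `p_min + 3 s_min` test) and is reset
  when it fires.
* **Streaming random patches** (`kind = "srp"`): the same bagging
  scheme, but each base tree trains on a fixed random *patch* (default
  60% of the features), re-drawn when drift resets the tree.

The Hoeffding tree uses per-class Gaussian summaries of each candidate
feature (weighted Welford updates), evaluates ten candidate thresholds
per feature by information gain, and splits when the Hoeffding bound
`sqrt(ln(1/delta) / 2n)` separates the best candidate from the
runner-up (or the tie threshold 0.05 is reached), with a grace period
of 50 examples between attempts and a depth cap of 12. These ensembles
are this package's own implementations, deliberately compact: there are
no background trees during drift warnings and the base learner is a
plain Hoeffding tree rather than an adaptive-tree variant. They are
streaming learners with drift recovery, not bit-compatible replicas of
any particular reference library.

Every classifier owns a private RNG stream seeded at construction, so
two classifiers with the same configuration and seed produce identical
prediction sequences regardless of what else draws random numbers in
between — asserted as a contract test.

## Evaluation protocols

**Progressive (test-then-train) validation**: each labeled vector is
first classified, the prediction is scored and the running confusion
counts and metrics updated, and only then is the model trained on it.
Every sample serves both roles. Metrics follow the confusion-count
definitions: accuracy `(TP+TN)/(TP+TN+FP+FN)`, F1
`TP/(TP + (FP+FN)/2)` (defined as 0 with a warning when no positives
exist anywhere), and macro F1 as the mean of the F1 with *high* and
with *low* as the positive class.

**Delayed progressive validation**: vectors are classified on arrival
with the current model and buffered. When a label tuple arrives, every
buffered prediction inside its interval is scored — one metric update
per prediction, so trajectories remain comparable across protocols —
and the model is then trained on those samples in window order.
Predictions made after that use the updated model. In the zero-delay
limit (each window's tuple arriving at the window's end) the procedure
is *identical* to progressive validation, which is asserted exactly in
the tests. Label tuples matching no buffered prediction warn rather
than fail, and never-scored predictions are reported.

**Shuffle repeats**: the repeated-evaluation protocol for recorded
data runs `k = 10` seeded shuffles of the full labeled set, each
evaluated prequentially with a fresh classifier, reporting per-repeat
finals and their mean/sd. This is the reading of "k-fold with
progressive validation" compatible with every sample being used for
both training and validation; a classic held-out-fold mode
(`mode = "holdout"`) is exposed for comparison, in which each repeat
trains prequentially on the other folds and only scores its held-out
fold.

`run_immediate()`, `run_window_sweep()` and `run_delayed()` orchestrate
the three experiment settings; `run_delayed()` supports both the
two-part live protocol (train an initial model on the shuffled first
part, resume with delayed validation on the second) and an induced
fixed delay (default 86 windows of 1 s — the mean stimulus length) on a
single recording. Each run can write a predictions log, a metrics
summary and a reproducibility metadata record.

## The synthetic generator

`generate_session()` emulates the data-collection protocol: 16 videos
(4 per valence–arousal quadrant, seeded random order), durations drawn
from a normal with mean 86.7 s and sd 27.8 s clamped to 51–150 s, a
10 s lead-in and 5 s inter-video gaps standing in for self-report
pauses. The signal per channel is a sum of five in-band sinusoids
(seeded frequency and phase) with baseline amplitudes 20/10/15/8/5 µV
for delta–gamma — a plausible consumer-EEG magnitude ordering — plus
1/f-shaped pink noise (10 µV sd) and 50 Hz line interference (20 µV,
large enough that the notch matters). Class structure is injected
multiplicatively on band *amplitudes* (high valence ×2 on alpha, high
arousal ×1.8 on beta by default), hence approximately quadratically on
band powers, making effect sizes directly interpretable against the
power and ratio features. Ratings are emitted at 0.75/0.25 ± Gaussian
noise (sd 0.05) and clipped to [0, 1], so the 0.5 threshold recovers
the intended class except when rating noise crosses it — a controllable
label-noise rate.

What the generator does *not* emulate: event-related potentials, ocular
and movement artifacts, electrode drift, inter-channel correlation
structure, or any non-stationarity beyond the stimulus-locked amplitude
steps. Passing recovery tests on synthetic sessions therefore
demonstrates that the pipeline's plumbing, features and learners work
end-to-end and can recover band-power class structure at realistic
SNR; it does not certify classification performance on real EEG.

## Problem sizes used in the checks

The structural and protocol tests run on small in-code fixtures
(dozens to hundreds of windows). The synthetic-recovery checks use
full-scale default sessions — 16 videos, about 1 400–1 700 one-second
windows each — with a single strong-effect subject (two shuffle
repeats) and ten null-effect seeds for the chance-level check, and one
paired immediate-vs-86-window-delay comparison. These sizes give
stable stochastic margins while keeping the whole suite in the
low minutes on one CPU.

## Known limitations

* Per-window stateless filtering accepts edge transients in exchange
  for window independence; the band-pass at a 0.5 Hz lower edge in
  particular cannot fully express its DC rejection within one second.
* The ensembles are compact re-implementations (see above); studies
  that depend on a specific reference implementation's drift behavior
  should treat results as qualitatively, not numerically, comparable.
* The linear band-power feature schema is fixed by design: no feature
  selection, log/relative powers, connectivity or fractal features.
* Only binary high/low classification of valence and arousal is
  supported; dominance/liking and multiclass basic emotions are out of
  scope.
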