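---
title: "Chest-accelerometer posture recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chest-accelerometer posture recognition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturekit)
```

## The sensing model

A tri-axial accelerometer strapped to the chest measures, in its own device
frame, the sum of the gravity field and movement-induced (dynamic)
acceleration, in units of g (1 g = 9.81 m/s²). For the four *static*
postures of interest — standing, sitting, bending, lying — the dynamic part
is small, and the information-bearing quantity is the direction of the
gravity vector relative to the trunk. We summarise it as the chest-tilt
angle

α = arccos( v · r / |v| ),

where `v` is the (low-passed) acceleration vector and `r` the unit
reference direction stored during calibration. Because `r` is measured on
the wearer, per-subject mounting offsets cancel: a sensor strapped on 5°
askew reads the same α as a perfectly aligned one.

Streams enter the pipeline as tibbles (`t, ax, ay, az[, label]`) with the
sampling rate as an attribute. Raw sensor counts are converted per axis by
the affine model `g = (raw − offset) / sensitivity` (default sensitivity
660 raw units per g, zero offset) and clipped to the ±2 g sensor range —
clipping, not rejection, mirrors a saturating part, and the clip count is
reported.

## Pre-processing

Electrical and environmental noise sit well above the postural band, so
each axis passes an order-8 Butterworth low-pass with 10 Hz cutoff. Two
modes are provided:

* `zero_phase` (batch default): forward–backward filtering. It cancels
  group delay — a filtered event stays aligned with its timestamps — at the
  price of squaring the magnitude response (the effective attenuation order
  doubles). We pad the signal by odd reflection, at least three filter
  lengths and three cutoff periods, before the double pass; without
  padding, the start-up transient of the recursion visibly corrupts the
  stream edges (even a constant signal acquires edge ripples).
* `causal`: one forward pass, exactly what a sample-by-sample real-time
  implementation produces.

The digital design uses the bilinear transform, so its response deviates
from the analog Butterworth closed form `1/√(1+(f/f_c)^{2n})` as `f`
approaches the Nyquist frequency (frequency warping): at a 50 or 100 Hz
sampling rate the measured attenuation at `2 f_c` is roughly twice the
analog prediction. Our magnitude-response tests therefore verify the closed
form at a sampling rate where the cutoff is far below Nyquist (1 kHz), and
treat the warped response at 50 Hz as the correct behaviour of a digital
filter rather than as an error.

**Calibration.** Right after the device is strapped on, the wearer stands
still for a few seconds. The check requires (a) |mean| ≤ 0.15 g on both
axes orthogonal to gravity, (b) gravity-axis mean within 0.15 g of 1 g, and
(c) every per-axis standard deviation ≤ 0.05 g (the wearer really was
static). Both tolerances are configurable; the defaults are our choice, as
is applying the check to filtered data (noise-robust). On success the
normalised mean vector becomes the tilt reference. Which device axis
carries gravity when standing depends on how the band is worn, so it is a
parameter (`gravity_axis`, default `z`).

## Windowing and features

Windows of 350 ms advance in 50 ms steps, one classification per window —
short enough for real-time feedback, long enough (17.5 samples at 50 Hz)
for stable statistics. Sample counts use a ceiling rule
(`window = ⌈350·fs/1000⌉`, 18 at 50 Hz, 9 at 25 Hz; step 3 and 2), so every
window covers at least the nominal duration at any rate.

Per axis and window, thirteen time-domain families are computed (all
moments are population moments, 1/N):

| family | definition | notes |
|---|---|---|
| MAV | Σ\|aᵢ\|/N | mean absolute value |
| STD, VAR | √VAR, Σ(aᵢ−μ)²/N | STD defined as √VAR |
| MAX, MIN, DAC | extrema; DAC = MAX − MIN | range of the filtered signal |
| RMS, SSI | √(Σaᵢ²/N), Σaᵢ² | SSI = N·RMS² exactly |
| WENT | −Σ pᵢ ln pᵢ, pᵢ = aᵢ²/Σaⱼ² | Shannon entropy of the normalised energy distribution; 0·ln 0 := 0 |
| SKEW, KURT | m₃/σ³, m₄/σ⁴ | 0 when σ < 10⁻¹² |
| SAC | range of the static component | see below |
| LEE | Σ log₂(aᵢ² + ε), ε = 10⁻¹² | log energy entropy |

Two definitions deserve comment. A literal "−Σ aᵢ ln aᵢ" entropy is
undefined for negative accelerations, so WENT is computed on the window's
normalised energy distribution, the standard signal-entropy construction;
similarly LEE uses `log₂(a² + ε)` to stay defined at zero. Both deviations
are deliberate and documented here rather than hidden.

The **static component** is the gravity projection isolated by a very low
cutoff low-pass (0.5 Hz, order 2). Order 2 rather than 8 is our choice: at
a normalised cutoff of 0.02 a gentle drift tracker is numerically safer
and, unlike the main filter, nothing here needs a sharp transition band.
DAC is the range of the main filtered signal in the window; SAC the range
of the static component — together they separate movement-induced change
from orientation change.

Window labels (when training) are the majority sample label, ties resolved
towards the label appearing earlier in the window.

**Feature selection.** `lasso_select()` fits an L1-penalised multinomial
linear model on the standardised columns and aggregates |coefficients| to
family level (max over classes and axes). With strongly correlated families
(MAV, MAX, MIN and RMS all encode the per-axis level; STD and VAR are
functions of each other) the lasso's surviving representative within a
correlated block is data-dependent. The pipeline therefore fixes its
working set to {MAV, VAR, DAC, SAC, KURT, SKEW} — the selection outcome the
tooling ships with — and exposes `lasso_select()` to reproduce and inspect
the procedure rather than re-running it on every fit. Whether selection
should act on per-axis columns or whole families is genuinely open; we
aggregate to families, which keeps the three axes of a family together and
makes the selection interpretable.

## Classifiers

* **Random forest** — 25 gini trees, depth ≤ 30 (`ranger` backend; seeds
  are shifted by one before reaching ranger, which treats 0 as "unseeded",
  and predictions carry a fixed tie-break seed, otherwise repeated runs of
  an identical experiment can differ in tied votes).
* **Decision tree** — gini, depth ≤ 19 (`rpart`, with `cp = 0`,
  `minsplit = 2` so the depth cap is the binding control). For
  single-window prediction the fitted tree is traversed directly; the
  formula-interface prediction path costs more per call than evaluating
  the tree itself, which would distort latency comparisons.
* **k-nearest neighbours** — k = 13, Minkowski p = 2, votes weighted by
  inverse distance; a query coinciding with training points is decided by
  those exact matches. Features are standardised with training-fold
  statistics (distances need comparable scales; tree models consume raw
  features). The neighbour search computes squared distances by a BLAS
  Gram expansion and selects/votes in a small compiled kernel. The
  Minkowski exponent p = 2 (Euclidean) is the metric's conventional
  default.

All models store the feature schema and refuse mismatched prediction
inputs; columns are aligned by name. `grid_search()` does an exhaustive
pass over a candidate grid with stratified validation folds, ties resolved
towards the earlier grid point.

## Evaluation protocol

Counts are reduced one-vs-rest per class: TP, TN, FP, FN. Overall accuracy
is the fraction of correctly classified windows; precision, recall and F1
(`2TP/(2TP+FP+FN)`) are computed per class and macro-averaged — with four
balanced classes, macro averaging is the standard choice; per-class values
are always reported alongside. Degenerate 0/0 ratios are reported as 0 with
a warning.

**Cross-validation.** Ten folds; per repetition 8 folds train (80%), one is
held out for validation (10%, available for model selection) and one for
testing (10%). Because consecutive windows overlap by 300 of 350 ms,
fully random folds would leak near-duplicate rows between train and test.
Fold assignment is therefore *grouped*: all windows from one contiguous
posture bout (one subject's uninterrupted segment) share a fold. Groups are
stratified by posture, and one subject's repeated bouts of the same posture
are spread across different folds, so every fold sees every class and every
subject is still tested on bouts the model never saw. With 7 subjects and
10 folds, subject-level grouping is arithmetically impossible; bout-level
grouping is the leakage-safe protocol that preserves the 10-fold shape.
Ungrouped stratified folds remain available (`group = NULL`).

**Downsampling experiment.** `downsample_cohort()` decimates 50 → 25 Hz
after the 10 Hz low-pass (which already acts as the anti-alias filter,
10 < 12.5 Hz Nyquist); windows are re-derived with the ceiling rule. This
probes whether halving the sensor rate — halving radio and compute load —
costs accuracy.

## The synthetic cohort

Real chest recordings of elderly wearers are not distributable, so the
package carries a generator whose defaults define the benchmark conditions:
7 subjects, 3 cycles of 30 s per posture at 50 Hz, tilt means 0° / 20° /
60° / 90° for standing / sitting / bending / lying with angular jitter of
4° / 5° / 8° / 6°, white sensor noise of 0.02 g per axis (±10% per
subject), a 0.005 g breathing sinusoid at 0.25 Hz along the chest normal,
cosine-interpolated 1 s transitions (transition samples carry the incoming
posture's label), and per-subject mounting offsets drawn with 3° standard
deviation about the device x and y axes. Sitting deliberately sits closer
to standing than to bending — the hard confusion pair for a single chest
device. Noiseless vectors have magnitude exactly 1 g by construction.

Two modelling choices matter for interpreting results:

* **Tilt jitter is fast (per-sample), not slow.** The spread parameters
  describe within-bout postural tremor around a fixed per-posture mean.
  Window averaging then shrinks the effective tilt noise by ~√N, so the
  classes are nearly separable and cross-validated accuracies land near
  the ceiling. Real data additionally vary *between* bouts and between
  days (a person's "sitting" is not one angle), which this generator does
  not emulate — passing the synthetic benchmark therefore demonstrates the
  pipeline's correctness and its noise behaviour, not field accuracy.
* **Calibration is a separate guided acquisition.** The calibration hold
  is simulated as a deliberately still stance (tilt jitter halved), as the
  fitting protocol instructs, rather than cut from natural activity; with
  the activity-level jitter the filtered y-axis deviation straddles the
  0.05 g static threshold and the check would fail sporadically by design
  of the threshold, not by fault of the wearer.

`simulate_cohort()` is seed-deterministic end to end and carries its
per-subject parameters (offsets, seeds, noise scales) as an attribute, so
an experiment is reproducible from a single integer.

## Real-time benchmarking

`benchmark_inference()` replays a stream window by window, timing the full
per-window path (slice → features → prediction), and compares the mean
latency with the sensor sampling period (20 ms at 50 Hz): a deployment is
real-time capable iff it classifies each window before the next sample
arrives. Absolute times are hardware-bound, so the package's tests only
assert machine-relative facts — the decision tree beats the forest, and the
real-time flag is computed, never assumed. CPU and memory percentages are
sampled from the running process via `ps`, degrading to an "unavailable"
marker on platforms without it.

## Problem sizes and numerical choices

The shipped experiment sizes — 7 subjects × 360 s × 50 Hz ≈ 126,000
samples and ~42,000 windows per replicate, five replicates — were chosen so
a complete evaluation of all three classifiers plus the 25 Hz variant runs
in minutes on a single core while keeping ≥ 1,000 windows per class per
fold. Tolerances: feature identities hold to 1e-9–1e-10 (double-precision
accumulation order); tilt angles clamp their cosine into [−1, 1] before
`acos`; variance is computed as `E[x²] − μ²` clipped at 0; σ below 1e-12
short-circuits the standardised moments to 0; KNN exact-match threshold is
1e-8 in distance. Degenerate inputs (streams shorter than a window,
single-class labels, empty matrices, zero-magnitude vectors) raise typed
conditions (`posturekit_*_error`) rather than propagating NaNs.

## Known limitations

* The generator's single-axis tilt kinematics (rotation about x, plus a
  static mounting rotation) cannot produce twisting or asymmetric
  postures, falls, or gait.
* Between-bout and between-day tilt variability is not modelled (see
  above); synthetic accuracies are ceilings, not field estimates.
* Lasso selection among correlated family blocks is data-dependent;
  the shipped six-family set is a fixed convention, not a per-dataset
  optimum.
* CPU/RAM sampling reports whole-process percentages; it is not a power
  model and no attempt is made to estimate energy consumption.
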