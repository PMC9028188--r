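---
title: "Gait-phase segmentation from wearable sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-phase segmentation from wearable sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwear)
```

`gaitwear` is a pipeline for recognizing gait phases — right swing + left
stance (`RSWLST`), right stance + left swing (`RSTLSW`) and double support
(`RSTLST`) — from wearable sensor streams: ten resistive textile pressure
channels sewn into pants and nine IMU channels (tri-axial acceleration,
angular velocity, magnetic field), both sampled at 100 Hz. Reference labels
come from a camera watching the walk, via a rule on pose-landmark
velocities. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic data can and cannot establish.

## The simulated trial

Real recordings of this protocol are not publicly distributable, so the
package ships a simulator whose output has the statistical structure every
downstream stage relies on. One trial: the participant stands mid-path,
performs three short jumps (the synchronization landmarks), then walks back
and forth along a straight 3.5 m path at 0.7 m/s, pausing ~1 s at each end
to turn. Samples whose body-center position falls in the outer 15% of the
camera frame are ground-truth `NC` ("not considered"): people decelerate
and turn there, so those samples do not represent steady walking and are
excluded from modelling.

**Gait schedule.** Each stride repeats double support → left swing → double
support → right swing. We use slow-gait proportions consistent with the
0.7 m/s pace: stride period 1.4 s, stance 65% of the cycle per foot, double
support 15% per transition (episodes of 0.21 s). These satisfy the symmetric
two-leg consistency condition `stance = 0.5 + double_support`. They are
conventional values for slow adult walking, not fitted to any particular
cohort: the protocol being emulated reports no cadence or stance/swing
ratios, so these defaults are the package's own choice and tests that depend
on them say something about the method, not about any specific population.

**Keypoints.** A 33-landmark schema at 60 frames/s in normalized image
coordinates (origin top-left, y downward). Stance feet are stationary; swing
feet follow a trapezoidal velocity profile (6% rise/fall), which makes the
swing-speed threshold crossing sharp — within ~1 frame of the true phase
boundary. Landmarks carry i.i.d. jitter (`keypoint_noise_sd`, default
5e-4 image units ≈ 2 mm at scene scale, i.e. a well-smoothed pose model).
Jumps displace the whole body vertically with a Gaussian bump.

**Sensors.** Each textile channel is a smoothed phase-keyed loading wave
(high while its leg bears weight, with a per-channel within-cycle shape),
multiplied by a gain drawn once per recording from a log-normal with median
1 and log-sd `gain_spread` (default 0.4). The log-normal keeps gains
positive and multiplicative — the natural model for resistive sensitivity
variation between hand-made sensors. Drift is an Ornstein–Uhlenbeck process
with the sensors' 17 s recovery time constant. Dropouts (whole-sample
transmission failures, flagged `valid = FALSE` with missing values) and
spike outliers are injected at configurable rates. IMU channels carry
phase-keyed patterns: vertical impacts at each foot strike, swing-side
signed angular velocity, heading-dependent magnetometer — plus large
acceleration spikes at the jumps. Camera and acquisition clocks have
independent configurable offsets, so synchronization has a real misalignment
to recover.

**What the simulator does not model:** biomechanically faithful joint
angles, 3D perspective, pose-model failure modes other than jitter and
occlusion, inter-stride variability of the gait schedule, and nonlinear
sensor compression. Passing tests therefore demonstrate that the pipeline's
machinery is correct and well-calibrated under its stated assumptions — not
that any particular precision will be achieved on real walkers.

## The auto-labeler

Per landmark, speed at frame *i* is the Euclidean displacement from frame
*i−1* over the time step, scaled by `pixel_to_meter` (default: 3.5 m path
spanning the central 86% of the frame ⇒ ≈ 4.07 m per image unit). A foot is
*swinging* iff max(heel, toe speed) exceeds `swing_speed_threshold`. The
threshold defaults to **0.35 m/s — half the nominal walking pace**: stance
feet are nearly stationary while swing feet move at roughly twice the body
speed (≈ 1.8 m/s here), so any threshold well inside that gap works, and
half the pace is a natural calibration that needs no tuning. It remains a
configuration parameter because the original protocol states the calibration
inputs (pace and camera distance) but not the resulting value.

Three design choices deserve comment:

* **Speed smoothing** (3-frame centered moving average, on by default):
  raw per-frame differencing amplifies pose jitter into apparent speeds of
  the same order as the threshold; the average damps it at the cost of ~1
  frame of latency at transitions.
* **Both-feet-swinging frames** carry the previous label forward: walking
  has no flight phase, so such frames are sensor noise (or a jump), not a
  gait state.
* **Body center** for the NC rule is the mean hip x-coordinate — the
  reference point is otherwise unspecified, and hips are the most stable
  landmarks.

Labels are emitted at 10 Hz across the track span. On noiseless synthetic
tracks the labeler agrees with ground truth on ≥ 99% of events outside ±2
frames around phase transitions; with realistic jitter, double support keeps
the highest per-class precision (misreading a stationary foot as swinging
creates single-support false positives, while swing speeds are far above
threshold, so the reverse error is rare).

## Synchronization

The label clock (camera/execution time) and the acquisition clock disagree
by an unknown offset. Both streams record the three pre-trial jumps, which
appear as the most prominent excursions of (a) the acceleration magnitude
and (b) the inverted mean heel height. Detection picks the expected number
of highest-prominence peaks of the rectified, median-detrended signal with a
minimum separation (default 0.5 s — the jumps are short, and the exact
spacing is not specified). The offset is the **mean** of the three pairwise
differences (averaging halves single-jump timing error); the residual (max
deviation from the mean) diagnoses mismatched detections. Interpolation of
10 Hz labels onto 100 Hz samples is previous-value carry-forward — labels
are categorical, so linear interpolation is meaningless; samples outside the
label span are `NC`. Recovery accuracy is ≈ half a sample (5 ms), well
within the 0.1 s label period.

## Preprocessing

The chain is fixed: NC removal → invalid-sample removal → outlier
replacement → low-pass → normalization, each stage logging sample counts.

* **Outliers:** a point is flagged iff it deviates from the channel median
  by more than 3 scaled MADs (scale 1.4826, the conventional consistency
  factor); this replicates the cited robust detector's documented default,
  since only the function, not its settings, is named. Each outlier is
  replaced by the **mean + sd of the non-outlier points**. Two notes: the
  replacement statistic excludes the flagged points (including a 100× spike
  in its own replacement would defeat the step), and the replacement is the
  same regardless of the outlier's sign — a documented oddity of the stated
  rule, kept as stated. When the scaled MAD is zero (over half the points
  identical) the detector degenerates and falls back to interquartile
  bounds, with a warning.
* **Filtering:** 5th-order Butterworth low-pass at 20 Hz. We apply it
  forward–backward (zero phase) because the labels are time-aligned with
  the signals and a causal 5th-order filter at these rates would introduce
  label-relevant group delay; `causal = TRUE` restores the single pass. The
  series is extended by odd reflection (36 × order samples) before
  filtering so the filter state settles outside the retained range; without
  padding, the edge transient on a constant signal is ~0.3%, with padding
  it is below 1e−12.
* **Normalization** is per channel over the full recording, mean 0 / sample
  sd 1. Computing it over the full recording before the train/test split is
  mild leakage — acknowledged; the offline protocol being reproduced
  normalizes whole recordings, and the split utilities accept
  already-normalized data. Constant channels normalize to zeros with a
  warning.

The conditioned recording is exported as two ARFF files (textile and IMU)
with identical timestamps and class labels.

## Windows, features, selection

Instances are sliding windows over contiguous sample runs (runs break where
NC/invalid removal left gaps). **Window 0.2 s (20 samples), stride 0.1 s,
majority labeling at 60%.** The window must be short enough that the
shortest phase — double support, 0.21 s under the default schedule — can
still win a 60% majority; longer windows would simply never produce
double-support instances, and ambiguous boundary windows (no 60% majority,
or a tie) are discarded rather than mislabeled. How the original study
formed instances is unstated, so instance counts are comparable in order of
magnitude only, not reproducible.

Each window yields 22 statistics per channel (a fixed, documented catalog
rather than a sprawling automatic one — reproducibility over breadth):
moments, order statistics, RMS and absolute energy, zero/mean crossings,
autocorrelation at lags 1–3, the least-squares slope per sample, and DFT
summaries (dominant frequency, band energies 0–5 / 5–10 / 10–20 Hz,
spectral centroid). Undefined values on degenerate windows (e.g. kurtosis of
a constant) are emitted as 0 with a warning. That is 220 textile and 198 IMU
candidate features.

Relevance selection: per feature, a one-vs-rest two-sample Wilcoxon
rank-sum test per class (no normality assumption on pressure-derived
features), feature p = Bonferroni-corrected minimum across classes, then
Benjamini–Yekutieli FDR control at 0.05 across features. BY is chosen over
Benjamini–Hochberg because feature columns are strongly dependent and BY is
valid under arbitrary dependence. On default synthetic data ~180–200
textile features survive — the same order of magnitude as the ~270 reported
for the protocol's real data. A Monte-Carlo test confirms a
class-independent noise feature is retained in well under 5% of tables.

## Classifiers and evaluation

**Random forest** delegates to `ranger` (500 trees, √p features per split,
seeded) on the selected feature table. Selection is computed on the training
partition only.

**Time series forest** is authored in the package: per tree, a bootstrap
resample (same size as the input, drawn with replacement) and
`⌈√w⌉·3` random intervals (start uniform, length uniform ≥ 3 samples); each
instance maps to the concatenation over intervals × channels of the interval
mean, standard deviation and least-squares slope; one CART is fit per tree;
prediction is the majority vote with ties broken by class order of first
occurrence in training (deterministic). The base CART is written in C++ with
Gini impurity, presorted features, and deterministic tie-breaking (lowest
feature index, then lowest threshold); stopping rules are `minsplit = 10`,
`minbucket = 3`, `maxdepth = 20`. A single tree with one full-window
interval reduces exactly to a plain decision tree on per-channel
(mean, sd, slope) — the oracle equivalence the test suite checks.

**Splitting** is block-wise by default: the last 20% of each recording's
windows (in time order) form the test set, so 50%-overlapping windows never
straddle the partitions — a leakage the unstated original split method may
or may not have avoided. Random splitting is available.

**Evaluation** reports the count confusion matrix (rows = true labels,
columns = predictions), per-class precision = TP/(TP+FP) by column, overall
accuracy = trace/total, macro precision, and supports. Classes never
predicted get `NA` precision, flagged, never zero.

`run_experiment()` builds per-participant and pooled datasets for the
textile-only and IMU-only subsets — with 3 participants, 8 datasets and 16
evaluations — mirroring the individual-calibration question the sensors
raise. The benchmark at its default scale (3 × 3 min trials, default noise)
gives macro precision 0.90–0.94 for both algorithms on both sensor subsets,
and reproduces the characteristic error structure: the two single-support
classes are almost never confused with each other, while nearly all residual
error involves double support — the shortest phase, bordered by transitions
on both sides. A symbolic-sequence classifier used alongside these two in
the original protocol is out of scope here; `run_experiment`'s reports are
plain tables, so an external implementation can be benchmarked next to
these results.

## Problem sizes, determinism, degenerate inputs

The shipped tests run the benchmark at 3 participants × 3 min — large
enough that every dataset contains hundreds of instances of each class, yet
desk-scale. All randomness flows from one root seed through named child
streams (participant, stage, dataset), so any stage is independently
reproducible; identical configuration and seed reproduce every stream,
table and file byte for byte.

Degenerate inputs are defined rather than accidental: zero duration gives an
empty timeline; an all-NC recording empties with a warning; constant series
normalize to zeros with a warning; zero-MAD channels use the interquartile
fallback; empty instance sets, single-class tables, windows longer than the
data, and mismatched jump counts all raise informative errors.

## Known limitations

* The labeler's threshold, smoothing and body-center reference cannot be
  verified against the original system (unpublished values); they are
  exposed as configuration.
* Precision figures obtained on synthetic data characterize the pipeline
  under its own generative assumptions; they are not predictions for real
  participants.
* Normalization over the full recording leaks mild distributional
  information across the split (documented above).
* The per-sample labeling granularity is bounded by the 10 Hz label stream;
  events shorter than one label period cannot be represented.
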