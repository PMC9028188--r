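# gaitwear

Gait-phase segmentation from wearable textile-pressure and IMU signals.

## The problem

Clinical gait analysis needs to know, at every instant, which phase of the
gait cycle each leg is in: **single support** on either side (one foot
swinging) or **double support** (both feet on the ground). Camera-based
motion capture answers this accurately but confines the patient to a lab.
Low-cost resistive textile pressure sensors sewn into ordinary pants are an
attractive alternative — but hand-made fabric sensors have strong
sensitivity variability, drift and dropouts, so the question is whether
machine-learning classifiers can still recover the gait phases from them as
reliably as from a gold-standard inertial measurement unit (IMU).

`gaitwear` implements the full experimental pipeline for that question as a
reusable, tested R package:

1. **Synthetic trial simulator** — ground-truth phase timelines, 33-landmark
   pose keypoint tracks and 100 Hz sensor recordings (10 textile + 9 IMU
   channels) of a participant walking back and forth on a 3.5 m path at
   0.7 m/s, with three pre-trial synchronization jumps, per-channel
   log-normal gains, drift, noise, dropouts and outliers.
2. **Rule-based auto-labeler** — heel/toe speeds from consecutive keypoint
   frames; a foot is *swinging* iff max(heel, toe speed) exceeds a threshold
   (default 0.35 m/s, half the nominal pace); frames with the body center in
   the outer 15% of the image are *NC* ("not considered", turnaround zones);
   labels are emitted at 10 Hz. A precision scorer compares label streams
   per class: precision(c) = TP(c) / (TP(c) + FP(c)).
3. **Synchronization** — the three jumps are detected in both streams as the
   most prominent excursions; the clock offset is the mean pairwise
   difference; 10 Hz labels attach to 100 Hz samples by carry-forward.
4. **Preprocessing** — NC removal, invalid-sample removal, robust outlier
   replacement (median ± 3 scaled MAD; outliers replaced by mean + sd of the
   rest), zero-phase 5th-order Butterworth low-pass at 20 Hz, per-channel
   z-normalization (mean 0, sd 1), and a textile/IMU ARFF dataset split.
5. **Features** — 0.2 s windows with majority labels; 22 time/frequency
   statistics per channel; relevance selection by one-vs-rest Wilcoxon rank
   tests under Benjamini–Yekutieli FDR control.
6. **Classifiers** — a random forest (via `ranger`) on the feature table and
   a from-scratch **time series forest** (TSF): per tree, a bootstrap
   resample and a fresh set of random intervals, each instance transformed
   to interval (mean, sd, slope) per channel, one deterministic CART
   (compiled in C++) per tree, majority vote. Reports give per-class
   precision and confusion matrices (rows = true labels).

## Worked example

```r
library(gaitwear)

cfg <- gait_sim_config(duration = 30, rng_seed = 42)
sim <- simulate_participant(cfg)

labels <- generate_labels(sim$track, labeler_config())
sync   <- sync_streams(sim$recording, sim$track)
sync
#> <gait_sync> clock offset 0.0000 s (residual 0.0000 s) from 3 jumps

labeled <- attach_labels(sim$recording, labels, sync)
clean   <- preprocess_recording(labeled)
stage_log(clean)
#> # A tibble: 3 × 3
#>   stage         n_in n_out
#>   <chr>        <int> <int>
#> 1 drop_nc       3000  2232
#> 2 drop_invalid  2232  2228
#> 3 condition     2228  2228

inst <- segment_windows(clean)
table(inst$label)
#> RSWLST RSTLSW RSTLST
#>     54     53     52
```

The 30 s trial produces 3000 sensor samples; 768 fall in the turnaround
zones (NC) and 4 are transmission dropouts, leaving 2228 conditioned samples
and 159 windowed instances, roughly balanced across the three phases.

The full benchmark (3 simulated participants × 3 min, textile and IMU
subsets, per-participant and pooled, both classifiers — 8 datasets, 16
evaluations):

```r
bench <- run_experiment(n_participants = 3, duration = 180, seed = 11)
dplyr::select(tidy(bench), dataset, algorithm, macro_precision)[1:4, ]
#>   dataset               algorithm          macro_precision
#> 1 participant_1_textile random_forest                0.901
#> 2 participant_1_textile time_series_forest           0.917
#> 3 participant_2_textile random_forest                0.929
#> 4 participant_2_textile time_series_forest           0.929
```

Macro precision is 0.90–0.94 on every dataset for both algorithms; the two
single-support classes are almost never confused with each other, while most
residual error involves the short double-support phase — the same pattern
the sensors show on real walkers. `autoplot()` methods visualize timelines,
recordings, confusion matrices and benchmark tables; `tidy()`/`glance()`
return the tables.

One configuration file drives the whole chain:

```r
run_all(pipeline_config(rng_seed = 13), out_dir = "run1")
```

writes every intermediate (timelines, tracks, label streams, labeled
recordings, ARFF exports, selection reports, the precision table and a
per-stage sample-count log).

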