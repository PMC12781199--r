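---
title: "Automated labelling of intraoperative neuromonitoring EMG signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated labelling of intraoperative neuromonitoring EMG signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During thyroid and parathyroid surgery, intraoperative neuromonitoring
(IONM) records evoked electromyograms (EMG) of the vocalis muscle after
electrical stimulation of the recurrent laryngeal nerve (RLN, `R`), the
vagal nerve (`V`, upstream of the RLN) or the external branch of the
superior laryngeal nerve (EBSLN, `S`). The operating team annotates
selected signals with a three-character code — nerve, stimulation time
point (`1` before / `2` after resection), neck side (`l`/`r`) — e.g.
`V1l`, `R2r`. Roughly a fifth of stored labels are wrong (device or human
error), which poisons any downstream analysis or model trained on the
archive.

`ionmqc` re-implements an automated labelling system for this setting: a
multitask classifier predicts (nerve, side, position) for every stored
signal, with a calibrated per-prediction uncertainty, so that records whose
stored label disagrees with a *confident* prediction can be flagged for
manual review. Because clinical IONM archives are not publicly available,
the package ships a synthetic-surgery simulator that reproduces the
statistical structure the classifier exploits, making every stage testable
end to end.

## Record format

The C2 Xplore device stores one CSV row per evoked signal: 10 metadata
fields (stimulation time in ms since start of surgery, stimulation current
in mA, amplitude, onset latency, min/max peak latency in ms, stimulating
channel 1–2, recording channel 1–4, a baseline field and the label)
followed by 1400 waveform samples covering 70 ms at 0.05 ms resolution —
1410 fields in total. `read_operation_csv()` / `write_operation_csv()`
implement this dialect (delimiter and decimal mark configurable, since
German-locale exports are common). The device does not document the
on-disk column order; the order above is this package's convention,
asserted by round-trip tests. Amplitudes are stored verbatim ("device
units"): the hardware nominally reports millivolts while clinical
thresholds are quoted in microvolts, and we never rescale raw data
silently.

## The simulator and what it emulates

`simulate_operation()` generates all stored records of one surgery:

* **Latency structure.** Onset latencies are drawn from truncated normal
  distributions. The RLN profile uses the published observed moments —
  mean 2.5 ms, sd 0.7 ms, range 1.1–10 ms — and the right vagal profile
  4.2(0.8) ms. Because the published numbers are sample moments of
  range-limited data, the simulator solves for the parent normal whose
  *truncated* moments equal the quoted values (naive truncation of
  N(2.5, 0.7) at 1.1 ms would bias the mean by ≈ +0.04 ms). The left
  vagal profile (6.5(0.9) ms, longer conduction path) and the EBSLN
  profile (3.3(0.8) ms, overlapping the RLN band so that R↔S is the
  hardest pair) are synthetic conventions, as is every amplitude
  distribution (log-normal, median a few hundred device units).
* **Waveforms.** A damped single-cycle biphasic kernel
  (sin(2πs/P)·e^(−s/τ), class-dependent period and decay) starts exactly
  at the drawn latency, scaled so the sampled peak-to-peak excursion
  equals the drawn amplitude, on Gaussian baseline noise. The dominant
  peaks fall inside the first 25 ms and activity decays to the noise
  floor well before 70 ms.
* **Surgical protocol.** Each operated side follows the standard sequence
  V1, R1, [S1], R2, V2, [S2] at stereotyped times within that side's
  block; side order is randomized. Continuous monitoring (cIONM) adds an
  unlabelled automatic vagal stream (40 records per side by default — a
  real cIONM run stores thousands; the thinned stream keeps the same
  temporal structure at desk scale) and stimulates via channel 2, the
  indwelling vagal electrode. Intermittent monitoring (iIONM) stores few
  signals per label, sometimes fewer than three per side. Four recording
  channels have side-dependent gains with per-operation jitter; the
  channel with the highest amplitude is selected per record, mirroring the
  device's automatic channel selection. Occasional broadband artefact
  records carry free-text annotations.
* **Label errors.** `inject_label_errors()` corrupts each stored label
  independently with probability 0.20 (default), flipping side, nerve or
  position or substituting an annotation; ground truth is kept separately,
  so error-detection performance is measurable.
* **Case mix.** `default_scenario_mix()` uses the 1541:508 continuous to
  intermittent case ratio of the motivating archive.

The corpus driver derives one seed per operation from the corpus seed, so
corpora are byte-reproducible and any operation can be regenerated in
isolation. (A per-record seed level was considered and rejected: massive
reseeding adds RNG-quality risk without a reproducibility benefit beyond
what operation-level seeds give.)

What the simulator does **not** model: electrode displacement over time,
loss-of-signal events and their management, anaesthesia effects,
device-specific filtering, or realistic artefact morphology. Passing the
package's benchmarks therefore demonstrates that the pipeline recovers the
structure the simulator encodes — not clinical-grade performance on real
archives.

## Features

`build_feature_matrix()` converts standard-labelled records into a fixed
matrix, by default 216 columns:

| block | width | content |
|---|---|---|
| `emg_segment` | 125 | first 25 ms of the waveform, every 4th sample (the first of each group of four — a pure index selection, asserted against an indexing oracle) |
| `channel_means` | 4 | per-channel summary amplitude over the whole operation (mean by default, median selectable) |
| `first_peak` | 1 | recomputed first-peak latency |
| `label_time_points` | 48 | up to 4 normalized occurrence times per standard label (padding sentinel −1) |
| `stimulus_fields` | 3 | normalized stimulation time, current, amplitude |
| `channel_onehot` | 6 | recording channel (4) + stimulating channel (2) |
| `modality_onehot` | 2 | cIONM / iIONM |
| `extra_context` | 27 | per-label capped counts (12), device latencies (3), recomputed onset, segment peak-to-peak/RMS/peak time, neighbour gaps (2), record order fraction, amplitude ratios (2), operation duration, and the record's relative time inside each side's labelled block (2) |

The exact composition summing to 216 is a documented convention of this
package; every block is switchable and the number of time-point slots
configurable, so widths across roughly 150–280 are reachable (a warning
fires outside that range). Onset and first-peak latencies are *recomputed*
from the waveform (threshold crossing at k·σ of the pre-response noise
window, k = 5, three consecutive supra-threshold samples, sub-sample
linear interpolation of the crossing) because device-reported latencies
are unreliable; the device values are still included as features. The two
side-block relative-time features encode where the record falls inside
each side's labelled sequence — the whole-operation temporal context that
makes before/after-resection assignment possible at all, since side blocks
appear in random order within the surgery.

Numeric features are min–max scaled with parameters fitted on training
rows only and frozen for held-out data; indicator columns are left
untouched. The targets are the three one-hot blocks obtained by splitting
the label (`split_label()`), enabling one prediction head per sub-label.

## Model

`model_config()` / `train_model()` implement a multitask 1-D
convolutional-recurrent network: the EMG segment enters as a 125-step
sequence through two gated recurrent unit layers (reset-before-multiply
GRU variant), then two blocks of 1-D convolution + batch normalization +
ReLU + max pooling; the flattened trunk output is concatenated with the
context/categorical features and split into three softmax branches of 3,
2 and 2 classes. Dropout and L1/L2 weight penalties regularize the
network. Where metadata enters the network is not externally constrained;
joining it after the trunk is this package's convention
(`feed_mode = "sequence_all"` feeds everything as one sequence instead).

Training minimizes the sum of the three cross-entropies (equal weights)
with Adam, halves the learning rate when the validation loss plateaus
(factor 0.5, patience 5), and restores the parameters of the best
validation epoch. The default schedule is 80 epochs; the acceptance
benchmark uses 22 epochs at batch 128 on ~16 000 signals, which is past
the point where all three heads plateau on the synthetic task. The split
protocol is ceil(0.7 n) training rows with round(0.2 · |train|) of them
held out for validation — the convention that reproduces the published
11 414 / 4 891 / 2 283 accounting for n = 16 305 — and the remaining 30%
for testing. `repeated_runs()` repeats split + training `k` times
(default 15) and reports mean(sd) accuracy per head and phase.

All layers (GRU forward and backpropagation-through-time, im2col
convolution, batch norm, pooling, dropout, Adam) are implemented in the
package, with the recurrent time loop and im2col in compiled code;
analytic gradients are validated against central finite differences in the
test suite (worst relative error on the order of 1e-6). Sequences travel
as (B·T)×C matrices with time blocks stacked rowwise so every parameter
gradient is a single stacked matrix product.

Numerical conventions worth knowing: probability heads are softmax rows
(guarded by max-subtraction); cross-entropy clips probabilities at 1e-12;
batch norm uses ε = 1e-5 and momentum 0.9 running statistics for
inference; max pooling breaks ties toward the earlier sample; an odd
trailing time step is dropped by pooling; inference on large inputs is
chunked (1024 rows) to bound the im2col working set, which is exact
because inference batch norm uses running statistics.

## Uncertainty

`mc_dropout_predict()` performs up to 30 stochastic forward passes with
independent dropout masks (batch norm in inference mode), averages the
sampled class distributions into the final probabilities, and reports a
raw per-head uncertainty — by default the predictive entropy of the mean
distribution (nats); the mean per-class variance across samples is the
config alternative. "Varying dropout configurations" is interpreted as
independent masks at a fixed rate.

`fit_calibration()` models the training-set distribution of raw
uncertainties per (head, predicted class) as a Gaussian N(μ, σ), fitted
incrementally with Welford's single-pass update on a random subset of 330
training signals — never test rows. `calibrate_uncertainty()` maps a new
raw value to Φ((raw − μ)/σ), the probability that a training uncertainty
is at most the observed one, so values near 1 mean "atypically uncertain".
Cells with fewer than two observations or zero spread are flagged and
yield an `NA` sentinel (such records are always routed to review rather
than given a step-function CDF). `flag_for_review()` flags a record when
any head's calibrated uncertainty exceeds the threshold;
`label_file()` marks a *suspected mislabel* when the stored label
disagrees with the prediction while every head is confident (calibrated
uncertainty at or below the threshold).

## Evaluation

`confusion_matrix()` builds the combined 12-label matrix and the per-head
3×3 / 2×2 / 2×2 matrices. `roc_auc()` computes multiclass AUC as the mean
of pairwise class AUCs (Hand–Till, Mann–Whitney with midranks; the test
suite cross-checks against `pROC::multiclass.roc`). The "concatenated"
prediction is the joint 12-class distribution formed as the product of the
three head probabilities (heads treated as independent), renormalized per
row; how the three outputs are concatenated is not externally specified,
so this choice is documented here and the decoded-label agreement is
reported alongside. `outcome_categories()` stratifies records into
TP/TN/FP/FN one-vs-rest per class (nerve head by default) with their
calibrated uncertainties, the basis of the uncertainty-by-outcome
summaries.

## Design choices that were genuinely open

* **Feature composition.** Only the total (216) and the ingredient list
  are externally fixed; the per-block arithmetic is ours and every block
  is switchable.
* **Downsampling phase.** "One in four values" fixes only the rate; we
  keep the first of each group, asserted by the indexing oracle.
* **Mean vs median channel summary.** Both appear in the motivating
  description; mean is the default, median a config option.
* **Normalization.** Min–max to [0, 1]; a robust percentile variant was
  considered and left out to keep the normalizer a two-parameter object.
* **Uncertainty functional.** Predictive entropy of the mean distribution
  by default; per-class variance selectable. Both are standard MC-dropout
  readouts; the choice is exposed, not hidden.
* **Architecture scale.** Layer widths (GRU 24/16 by default, conv 16/16,
  kernel 5, dense 32) are chosen so training runs in minutes on one CPU;
  all are config, none hard-coded. The acceptance benchmark uses a
  slightly smaller trunk (GRU 16/12, conv 12/12, dense 48) for the same
  reason.
* **Problem sizes.** The benchmark corpus is 790 operations (~16 300
  labelled signals, matching the motivating table's scale); simulator
  recovery checks use 2000 draws; error-model checks 10 000 records.

## Known limitations

* The synthetic task is easier than clinical data: channel gains are
  stable within an operation, artefacts are rare and crude, and protocol
  deviations (the main clinical error source) are limited to random
  jitter. Accuracy numbers on the benchmark are internal properties of
  the pipeline, not claims about clinical performance.
* The Gaussian calibration assumes unimodal raw-uncertainty
  distributions per cell; with few MC samples the entropy statistic is
  discrete-ish and the Kolmogorov–Smirnov uniformity of calibrated values
  is only approximate.
* Training on one CPU bounds the practical architecture size; the config
  accepts larger networks but the defaults are deliberately small.
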