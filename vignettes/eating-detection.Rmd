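---
title: "Detecting eating from wrist-worn inertial sensors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting eating from wrist-worn inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

wristfork implements a complete analysis pipeline for detecting eating
events from passively collected wrist accelerometer and gyroscope streams
with self-reported diary labels, the setting of free-living smartwatch
studies. This vignette explains the models and procedures the package
implements, the parameters that matter, and the design decisions taken
where the protocol leaves genuine freedom.

## The data model

The atomic unit is one *participant-day*: a table of samples at a nominal
50 Hz carrying a timestamp (`ts`, epoch ms), local time (`tod`, seconds
since midnight), a recording-session index (`sesid`; a day often contains
several sessions because watches come off and recording restarts), triaxial
acceleration in g, triaxial rotation rate in rad/s, six binary utensil
flags, and three diary labels: `tag` (any eating tag), `tagTimely` (the tag
was entered while eating) and `tagRetro` (the interval was reconstructed
afterwards; missing when never set). With the participant id and date
carried in the file name, this is a 20-feature record. `read_day()` /
`write_day()` move it through plain CSV; `extract_meals()` recovers diary
meal events as maximal runs of `tag == 1`.

Retrospective labels deserve their special treatment: a participant typing
in a rough interval hours later produces boundaries that cannot be trusted
to window precision, so such intervals are neither positive nor negative
examples — they are excised (label −1, below) rather than trusted or
discarded silently.

## The synthetic cohort

The study data such pipelines are built on are not publicly shareable, so
the package ships a generator (`gen_config()`, `simulate_day()`,
`simulate_cohort()`) whose defaults encode the free-living recording
structure the analysis assumes:

* days start between 7 and 9 AM and end between 7 and 9 PM (8–15 h of wear);
* 1–7 diary meals per day, the bulk of days having 1–4;
* log-normal meal durations (median 12 min, log-sd 0.757) putting ~75% of
  meals under 20 minutes, truncated to [2, 90] min;
* meal start times drawn from a three-mode mixture at breakfast, lunch and
  dinner (7:45, 12:15, 18:30; sd 45 min);
* about a third of days contain 1–3 recording gaps of ≥ 5 min, which
  increment `sesid`;
* a configurable fraction of meals (default 10%) is tagged retrospectively;
* occasional watch-off stretches where all six channels collapse to
  near-zero.

Eating itself is modeled at the gesture level: a bite is a smooth
raised-cosine rotation pulse (default peak 1.2 rad/s, 1–2.5 s long,
dominant on one gyroscope axis with a correlated, much smaller acceleration
bump) repeating every 4–7 s for the duration of the meal. The baseline is
band-limited AR(1) noise (gyro sd 0.25 rad/s) plus a per-day gravity
orientation on the accelerometer. Two confuser processes keep the task from
collapsing into a pure energy threshold: short arm-swing bursts (6/h,
5–20 s) and sustained walking-like oscillation bouts (0.4/h, 2–8 min,
0.9–1.4 Hz). Each participant gets jittered gesture parameters (axis mix,
amplitude, bite cadence), which is what personal fine-tuning has to adapt
to.

What the generator does **not** emulate: biomechanics (no articulated arm
model), smoking or tremor confounders, nondominant-hand wear, device
dropout jitter, or any utensil-specific kinematics (utensil flags are
carried but do not alter the signal). Tests passing on this generator
therefore demonstrate that the pipeline's machinery is correct and that the
training stack can recover planted structure — they do not certify
real-cohort accuracy.

`inject_noncompliance()` plants the failure modes the cleaning stage must
catch (watch-off segments, days under 3 h, all-retrospective labels, days
with no meals), so the cleaner can be tested with known ground truth.

## Cleaning

`clean_cohort()` applies three rules in order: drop participants whose
pooled fraction of retrospective meals strictly exceeds 50% (a participant
at exactly half is retained); drop days whose summed session duration is
under 3 h; drop days without any meal event. Watch-off stretches are
detected (5-minute rolling mean of the summed absolute motion below 10⁻³
per channel) and logged in the report but never removed — no removal rule
is part of the protocol, so the cleaner observes rather than invents one.

## Windowing and labels

`make_windows()` cuts each day into 300-second windows advanced by 20
seconds from the first sample of the day, over the concatenated sample
timeline. Labels:

* **1** — strictly more than 150 s of the window is tagged mealtime. The
  boundary matters: a window with exactly 150 s is negative.
* **−1** — excluded from training *and* evaluation when the window (a)
  spans two sessions, (b) overlaps any sample with `tagRetro` set, or (c)
  overlaps a meal shorter than 3 minutes. Excluded windows stay in the set,
  labeled −1, so exclusions are auditable.
* **0** — otherwise.

Two interpretive choices here. Windows are laid over the concatenated
sample timeline (not per-session), which is what makes condition (a)
reachable at all; and condition (c) marks only the windows overlapping a
short meal, not the whole day. Class balance is then restored on the
training partition only: `oversample_windows()` appends
`#negatives − #positives` positive windows drawn with replacement, leaving
evaluation sets at their natural imbalance.

## Normalization and augmentation

Per window and per axis, `center_window()` subtracts the mean and
`zscore_window()` additionally divides by the population standard deviation
(divide by *n*, pairing naturally with the per-window mean; an axis with
zero spread — a watch-off window — returns zeros rather than NaNs).
Centering is the default: it removes orientation offsets, which carry no
information about eating, while preserving signal magnitude, which does.

Training-time augmentation, applied on the fly and never on the inference
path:

* `scale_magnitude()` multiplies all channels of a window by one scalar
  drawn from U(0.8, 1.2), emulating gesture-vigor variation;
* `rotate_triples()` applies a single random 3-D rotation — uniform random
  axis, angle from (0, 2π), built by the axis–angle (Rodrigues) formula —
  to every timestep's (x, y, z) vector, emulating a differently oriented
  watch frame. When both sensors are present the *same* rotation applies to
  both triples, since they share the physical frame. One rotation is drawn
  per window (not per batch).

## The classifier

The backbone (`cnn_spec()`, `train_cnn()`) is a 1-D CNN of ten blocks, each
convolution (valid padding, stride 1) → batch normalization → ReLU →
max-pool, with filter counts 8, 16, 16, 32, 32, 64, 64, 128, 128, 256 and
kernel sizes 11, 10, 10, 8, 9, 6, 7, 4, 5, 2, followed by a global max-pool
over time and one fully connected sigmoid unit. Weights are
Glorot-uniform-initialized and trained with Adam (reference learning rate
3 × 10⁻⁵) on binary cross-entropy for 5 epochs, restoring the weights of
the epoch with the best validation performance ("best" defaults to minimum
validation loss; AUC is selectable, since the protocol's phrase "best
performance" does not pin this down).

Details the architecture description leaves open, fixed here as follows:

* **Pooling plan** — derived automatically: pool by 2 after a block
  whenever the remaining length still feeds all downstream kernels,
  otherwise by 1, with a global max-pool after block 10. At the full
  15000-sample input this pools by 2 after blocks 1–9. The plan is exposed
  in `cnn_spec(pools = )` for override.
* **Activation** — ReLU after batch norm; sigmoid output (implied by the
  binary cross-entropy target).
* **Batch size** — 64, exposed in `train_config()`.
* **Batch-norm statistics** — running mean/variance with momentum 0.1 for
  inference; this matters at very small training scales, where the running
  statistics need enough updates to converge (the toy-scale tests raise the
  momentum for that reason).

The network, its backpropagation (including through batch normalization and
max-pooling), and the Adam optimizer are implemented in the package's C++
layer (RcppArmadillo, im2col + GEMM convolutions); gradient correctness is
pinned by central-finite-difference tests.

## Ensembling, splits, and personalization

Evaluation is subject-wise throughout (`split_plan()` asserts that no
participant appears in more than one of train/validation/test). In the
reference design, 3 of 14 participants are held out as the test set, and 5
models are trained on 5 redraws of the validation pair from the remainder;
the inference score is the arithmetic mean of the 5 member scores
(`train_ensemble()`, `predict_ensemble()`). A leave-one-subject-out mode
trains one such ensemble per held-out participant.

`finetune_ensemble()` builds a personal model: the target individual's days
are split 60/20/20 into tuning, validation and held-out test days; every
member continues training for 2 epochs on the tuning days (balanced by
oversampling), restoring its best validation epoch. At least 5 recorded
days are required so the day split is non-degenerate; the protocol's
personal models are intended for individuals with ≥ 7 recorded days.

## Metrics

`window_metrics()` reports AUC (rank-based, ties counted half), AUPRC
(average precision over tied-score blocks) with its prevalence baseline,
precision, recall, weighted F1 (per-class F1 averaged with class-proportion
weights), and weighted accuracy

\[
\mathrm{WAcc} = \frac{w\,TP + TN}{w\,(TP+FN) + TN + FP},
\qquad w = \frac{\#\text{negatives}}{\#\text{positives}},
\]

the class-rebalanced accuracy convention of the wrist-sensor eating
detection literature. The exact printed equation in the protocol is a
figure placeholder, so this form — reconstructed from the cited
convention and the printed definition of *w* — is flagged as a
reconstruction. The default decision threshold for the confusion-based
metrics is 0.5, exposed as an argument.

`resample_compare()` is the paired resampling significance procedure: per
repeat, draw 1500 positive windows and 1500·R negatives, with R the
negative:positive imbalance ratio so the draw preserves the original
imbalance; compute each metric for both scorers on the shared draw; report
the one-sided p-value as the fraction of repeats where scorer A fails to
beat scorer B, ties counting one half (so two equivalent scorers sit near
0.5). An add-one continuity correction is available. One- versus two-sided
is a documented choice, not a claim about the original analysis.

## Meal-level aggregation and alarms

`score_meals()` aggregates window scores over diary meals: a meal's score
is the mean of the windows whose *midpoint* falls inside it (membership by
midpoint keeps short meals scoreable while never crediting windows that
merely graze a boundary). For every meal a negative region of identical
length is sampled from non-meal time on the same day, outside a 10-minute
guard band around every meal; comparing the two score sets gives meal-level
AUC and the thresholded metrics.

`detect_calls()` implements the alarm rule: windows are rescored on a
10-second stride (by inference on the denser grid, not interpolation); a
span of `horizon_minutes` (5 or 10) raises a *call* when strictly more than
N windows inside it exceed the score cutoff (defaults N = 3, cutoff 0.3; N
and the cutoff are the robustness dials). Per-meal recall asks whether a
call lands within the first horizon after the diary start.
`false_positive_rate()` counts call regions on meal-free time — consecutive
qualifying spans closer than one horizon merge into a single region, so one
sustained false detection counts once — divided by the evaluated hours. The
merge rule is a reconstruction chosen to avoid double-counting; the literal
"(false regions − positive regions)/hours" form is available through the
`positive_regions` argument, and is vacuous on purely negative streams.

One printed-number tension is worth recording: the alarm text states the
strict rule "> 3 windows" while the robustness figure sweeps N ∈ {1, 3}.
The package keeps N as a parameter with the strict `> N` comparison and
default 3.

## The scaled-down reference study

`run_experiment()` wires everything together; every stage's randomness
derives from one `master_seed`, so a rerun reproduces the report exactly.
The reference configuration used by `scripts/acceptance.R` and the
end-to-end tests is the full design at desk scale, all chosen once as the
package's own study conditions:

* 14 participants × 10 days, with the generator's default day structure;
* sensor synthesis at 3 Hz (bite pulses of 1–2.5 s remain well resolved;
  900-sample windows);
* per-day window subsampling: 10 positive + 15 negative windows per
  training day, 30 + 60 per evaluation day — meal-level regions, call
  horizons and the sampled negative hours are always scored in full;
* Adam learning rate 1 × 10⁻³: the subsampled run takes a few hundred
  gradient updates instead of tens of thousands, so the reference rate of
  3 × 10⁻⁵ would leave the network essentially at initialization; the rate
  is raised to match the update budget, with epochs kept at 5;
* false positives evaluated over 10 sampled negative hours of held-out
  days.

At this scale a full cross-validated run takes roughly 10–15 minutes on one
CPU. On it, the window-level ensemble AUC, the meal-level AUC against
matched negatives, the 10-minute call recall and the hourly false-positive
rate are recomputed from scratch; the tests assert the recovery properties
(window AUC ≥ 0.85, meal AUC ≥ 0.95, ensemble no worse than its best
member − 0.02, fine-tuning not hurting a gesture-shifted individual in at
least 4 of 5 replicates) rather than any real-cohort number.

## Numerical and degenerate-input conventions

* σ = 0 axes z-score to zeros; non-finite inputs abort with a data error.
* Days shorter than one window produce an empty window set, not an error.
* Oversampling with zero positives aborts; with positives already in the
  majority it warns and does nothing.
* AUC/AUPRC on single-class labels return NA with a warning while the
  confusion-based metrics are still reported.
* Meal events are half-open intervals `[start_ts, end_ts)`; window/region
  membership uses half-open comparisons throughout, so adjacent intervals
  never double-count a sample.
* All seeds are 32-bit integers; child seeds are derived with a fixed
  linear-congruential map so independent stages never share a stream.

## Known limitations

The generator's kinematics are deliberately simple; nothing here claims
biomechanical realism, and the reported synthetic AUCs are properties of
the planted structure, not forecasts for any cohort. The CNN runs on CPU
and at the full 50 Hz × 300 s input is sized for workstation training, not
embedded inference. The significance procedure assumes the two scorers
were evaluated on identical windows. Meal-level aggregation requires
enough non-meal time to place matched negatives; extremely meal-dense days
abort with an explicit error rather than silently reusing regions.
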