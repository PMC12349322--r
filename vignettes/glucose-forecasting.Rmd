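---
title: "Personalized probabilistic glucose forecasting with glucast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized probabilistic glucose forecasting with glucast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

People with type 1 diabetes steer their glucose with insulin dosing and meal
decisions made under uncertainty. A forecast of interstitial glucose 60
minutes ahead is clinically actionable — but a *point* forecast hides how
uncertain the model is exactly when it matters most (imminent hypo- or
hyperglycemia). `glucast` implements an end-to-end pipeline for
**multi-horizon quantile forecasting** of CGM (continuous glucose monitoring)
traces with an interpretable attention-based model, evaluated with
diabetes-specific accuracy criteria, and organized as an **incremental
input-feature study**: starting from CGM readings alone, covariates (subject
identity, calendar information, insulin and meal events) are added one at a
time to quantify what each contributes to accuracy and uncertainty.

Two data regimes are covered, mirroring the two kinds of CGM studies the
pipeline is designed around:

* **CGM-only, 15-min sampling, one year per subject** (29 subjects by
  default). Long records expose circadian, weekly and seasonal structure;
  calendar covariates (hour, day of week, day of month, month) are the only
  exogenous information. Six experiments: `cgm`, `+id`, `+hour`,
  `+day_of_week`, `+day_of_month`, `+month`.
* **Multivariate, 5-min sampling, two weeks per subject** (12 subjects by
  default), with carbohydrate intake (g), bolus insulin (U) and basal rate
  (U/h) event streams on their own clocks. Seven experiments: `cgm`, `+id`,
  `+hour`, `+day_of_week`, `+basal`, `+carbs`, `+bolus`.

Real cohorts of this shape are typically available only on request, so the
package ships a first-class, tested synthetic-data module that emulates both
regimes; every empirical claim in the test suite is made on data from this
generator and therefore speaks to the pipeline's correctness, not to any
real-world dataset.

## The synthetic cohort generator

`simulate_subject()` draws glucose as

```
G(t) = clamp( G0 + A sin(2*pi*(hour - phi)/24) + w[dow] + m[month]
              + sum_i c_i K_carb(t - t_i) - sum_j b_j K_bolus(t - s_j)
              + e(t),  40, 400 )  [mg/dL]
```

with per-subject parameters (`subject_profile()`): basal level `G0` in
[80, 180] mg/dL, circadian amplitude/phase, day-of-week and month offsets,
and AR(1) sensor noise `e(t)` with stationary standard deviation `noise_sd`.
Impulse responses are gamma-shaped kernels normalized to peak 1: a carb
response rising over ~30–60 min and decaying within ~2–3 h (peak height
`carb_sensitivity * grams`), and a bolus response with ~15 min onset, peak
near 75 min and a ~4 h tail (peak height `insulin_sensitivity * units`,
negative sign). These shapes are a deliberate modelling choice, not a
physiological model (no Bergman/UVA-Padova dynamics): they make meals and
boluses *visibly* drive glucose so that feature-importance recovery is a
testable property. Boluses accompany ~85% of meals within ±20 min and are
sized so their glycemic effect covers 70–105% of the meal's rise, keeping
excursions realistic instead of piling up at the 40 mg/dL sensor floor.
Meals are drawn around 08:00/13:00/20:00 (plus optional snacks) with a fixed
per-subject offset, creating an hour-of-day signal a model can exploit.

Two realism features force the preprocessing to do real work:

* **Reading interruptions** (`inject_interruptions()`): a Poisson number of
  gaps with mean `interruption_rate` per subject-week (default 1.5 — the
  source regimes report interruption histograms only in prior work, so this
  default is a package choice), each removing a contiguous run of at least
  two samples so every gap exceeds twice the sampling period.
* **Heterogeneous event clocks** (`jitter_event_timestamps()`): Gaussian
  jitter (default SD 60 s — sub-sample-period, but enough that event and CGM
  timestamps essentially never coincide) applied to every event timestamp.

Everything is a deterministic function of `(cohort_config, seed)`, and
timestamps are timezone-naive local time, from which all calendar covariates
derive.

## From raw traces to supervised instances

1. **Gap detection** (`detect_gaps()`): a new segment starts whenever the
   difference between consecutive CGM timestamps exceeds *two sampling
   periods minus one second* (29:59 min at 15-min sampling); imputation is
   deliberately not performed, so models only ever see gap-free windows.
2. **Common time grid** (`build_common_grid()`): grid slots at the sampling
   period span the first to last CGM timestamp; every CGM sample and event
   is assigned to its *closest* slot (exact midpoints break toward the
   earlier slot — a convention this package fixes, since closest-match
   assignment alone does not define it). If two consecutive CGM samples
   share a closest slot, the sequence is declared interrupted after that
   slot. Carb/bolus slots with no event are zero; the basal rate is carried
   forward until updated (and backwards before its first event).
3. **Sliding windows** (`generate_instances()`): stride-1 windows of `N = 96`
   input samples plus `H = PH / sampling_period` targets inside each
   segment; a segment of length `L` yields `max(0, L - N - H + 1)`
   instances. The default prediction horizon is PH = 60 min, i.e. `H = 4`
   (15-min) or `H = 12` (5-min).
4. **Splitting** (`split_instances()`): year-long cohorts are split
   60/20/20 within each (subject, calendar-quarter) stratum with
   largest-remainder rounding, after excluding instances whose span crosses
   a quarter boundary — this keeps all seasons represented in every set
   while preventing leakage. Trimesters are calendar quarters (Jan–Mar, …);
   anchoring quarters to each subject's first sample would be equally
   defensible, but calendar quarters make strata comparable across
   subjects. Short multivariate cohorts emulate a fixed pre-made partition
   with a chronological 65/16/19 split per subject.
5. **Normalization** (`fit_normalization()`): z-scores per real-valued
   feature, fitted **on the training set only** and reused unchanged for
   validation and test. Fitting on all subsets would leak test statistics
   into training; the package fits train-only as the safe reading of
   "all subsets were normalized". Normalization is global (per feature, not
   per subject): the subject embedding is the mechanism intended to absorb
   between-subject level differences.
6. **Feature encoding** (`encode_features()`): hour as a real in [0, 24),
   day of week categorical with the fixed Monday = 0 convention, day of
   month real, month categorical, subject id static categorical,
   basal/carbs/bolus real. Two auxiliary position channels — `time_index`
   (absolute position within the window) and `relative_time_index`
   (position relative to the prediction point) — are explicit input
   channels on a fixed [-1, 1]-bounded scale, so the decoder has inputs
   even in CGM-only runs and their importances can be reported.

## The forecaster

`glucast()` fits a compact temporal-fusion forecaster producing the 10th,
50th and 90th conditional percentiles for every horizon step:

* per-feature linear embeddings (categoricals via embedding tables);
* a **variable selection network** per side (encoder/decoder): a gated
  residual network over the concatenated feature embeddings emits softmax
  weights per time step — these weights *are* the feature importances;
* a **static covariate encoder** (subject embedding passed through gated
  residual networks) conditioning variable selection, the LSTM initial
  state and the enrichment layer — present only when `id` is among the
  features: unused components are skipped, not zeroed;
* an **LSTM encoder–decoder** for short-range dynamics;
* **interpretable multi-head attention** from decoder positions over the 96
  input positions, with value projections shared across heads and additive
  head aggregation, so the averaged weights are directly readable;
* gated linear units with residual skips around each stage, and a linear
  head emitting one value per quantile level.

Training minimizes the pinball loss `q(y - yhat)+ + (1-q)(yhat - y)+`
summed across quantiles and horizon steps (Adam, global gradient-norm
clipping, minibatches, dropout), keeping the weights of the epoch with the
best validation loss. The whole network and its gradients are implemented
on a small tape-based reverse-mode autodiff engine written in base R
(`R/autodiff.R`); gradient correctness is pinned by finite-difference
tests, and the LSTM is checked against a hand-stepped recurrence.

Numerical and design choices worth knowing:

* **Compact variant.** Gated residual networks omit layer normalization,
  and the variable selection network weights the raw feature embeddings
  (no per-feature nonlinear transform). Both cuts keep single-CPU training
  tractable at desk scale without touching the interpretability surface.
* **Hyperparameters are fixed defaults** (hidden 32, continuous hidden 16,
  2 heads, dropout 0.1, lr 1e-3, clip 1.0, batch 128, ≤ 50 epochs with
  patience 5), standing in for a per-experiment Bayesian search that is out
  of scope at this scale. `max_train_instances` draws a seeded subsample
  when a cohort yields more training windows than a desk-scale run needs.
* **Quantile crossing** is resolved by sorting the predicted quantiles per
  (instance, step) at prediction time.
* **Output-head biases** start at `qnorm(q)/2` in normalized units, so the
  three quantile outputs begin separated rather than collapsed.
* **Degenerate inputs**: a zero-variance real feature is rejected by name
  at normalization; traces shorter than two CGM samples, non-monotone
  timestamps, fractions not summing to one, and quantile sets without the
  median are all rejected with messages; a non-finite training loss aborts
  with a diagnostic rather than continuing.

## Evaluation

`metrics_report()` assembles, per experiment:

* **Deterministic metrics** — RMSE, MAE, MAPE (mg/dL, %) between the p50
  forecast and the truth, by default at the *last* horizon sample only
  (the full prediction horizon); a `full_sequence` mode covers every step.
  Whether the ISO-based metrics should also use only the last sample is
  not fixed by convention; the package defaults to last-sample for
  consistency and exposes the flag.
* **ISO 15197:2015 zone** — share of points within ±15 mg/dL (reference
  below 100 mg/dL) or ±15% (at or above 100), boundaries inclusive, with
  the ≥ 95% criterion flag.
* **ParkesAB** — share of points in zones A∪B of the Consensus (Parkes)
  Error Grid for type 1 diabetes, with the ≥ 99% criterion flag. The zone
  boundaries are hard-coded from the published construction coordinates of
  the grid (Pfützner et al. 2013); classification is piecewise-linear
  band membership, boundary-inclusive toward the safer zone, and a sweep
  test verifies every point of [20, 550]² receives exactly one zone.
* **q-risk** — the normalized quantile loss
  `2 * sum QL(y, yhat_q, q) / sum |y|` over all test instances and all
  horizon steps, per quantile; dimensionless, lower = less uncertainty.
  At q = 0.5 it equals `sum|y - yhat| / sum|y|`, which the tests use as a
  closed-form oracle.
* **Interval coverage** — the share of true values inside [p10, p90],
  nominally 80%.

## Interpretability

`predict()` returns an interpretability bundle alongside the forecasts:
attention weights over the 96 input positions per predicted step (averaged
over heads; reported by default for the first predicted step, where it is
representative), and encoder/decoder variable-selection weights averaged
over time and instances, renormalized to percentages
(`feature_importance()`). The static `id` is excluded from the comparison
(its selection weight is not commensurable with time-varying features) and
the decoder report never contains `cgm`, which is the target itself.
Averaging is over the full test set. `export_instance()` emits plot-ready
JSON records (input window, truth, p10/p50/p90, interval width per step)
for instance-wise uncertainty inspection.

## The incremental study

`run_study()` simulates one cohort per study, then trains, evaluates and
explains one model per feature prefix, so rows differ only in their
feature sets; every run is fully determined by `(config, seed)`.
`compare_rows()` reports per-metric deltas against the CGM-only baseline,
flags the best row per metric, and computes the Spearman rank correlation
between RMSE and the p50 q-risk across rows — the qualitative expectation
being that more accurate average-tendency prediction comes with less
uncertainty. Parameter counts are logged per row but deliberately not
asserted monotone in the number of features.

## Problem sizes and what passing tests show

The test suite and the acceptance script run, by choice, at desk scale:
coverage calibration uses a 5-subject × 30-day multivariate cohort
(≈ 40,000 windows, training on a 4,000-window seeded subsample for about
ten epochs); importance-recovery experiments use 2-subject × 14-day
cohorts with a 16-unit model; the study orchestration tests thin the
instance tables to a few hundred windows per set. These sizes are stated
here as the package's chosen experimental conditions.

The generator produces smooth additive seasonal structure, stationary
AR(1) noise and exactly periodic sampling jittered only at event level. It
does **not** emulate sensor drift and recalibration artifacts, compression
lows, meal-annotation errors, exercise, stress, or circadian phase shifts.
Passing tests therefore demonstrate that the pipeline's mechanics —
thresholds, alignment, splitting, loss, metrics, interpretability algebra
— are correct and that the model learns the structure this generator
contains; they do not certify clinical performance on real CGM data.

## Known limitations

* Single-CPU base-R training: minutes per experiment at desk scale;
  real-data scale would need the same architecture in a compiled
  framework.
* No missing-data treatment: interrupted windows are dropped, not imputed.
* Quantile regression only (no parametric likelihoods or MC-dropout), and
  no hyperparameter search per experiment.
* The Consensus Error Grid is the type-1-diabetes grid only.
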