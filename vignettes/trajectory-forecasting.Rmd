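---
title: "Forecasting clinical trajectories through a text-generation channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting clinical trajectories through a text-generation channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(twinforecast)
```

## The problem and the modeling idea

Electronic health records describe a patient as a sparse, irregular
multivariate time series: laboratory panels measured when a clinician orders
them, therapy events, ordinal performance scores, demographics. Classical
multi-step forecasters demand a rectangular design -- imputation,
normalization, aligned grids -- and most model each series independently,
even though clinical series are strongly cross-correlated (chemotherapy
suppresses hemoglobin *and* neutrophils; inflammation raises leukocytes and
neutrophils together).

`twinforecast` implements the alternative this package is organized around:
serialize each patient's history into plain text, fine-tune a generative
language model to continue that text with a JSON forecast, sample many
continuations, and average them. The text channel needs no imputation (a
missing value is simply not mentioned), handles mixed encodings, and models
all variables jointly in a single sequence. The fitted object -- a
`twin_forecaster` -- behaves like any R model: `predict()`, `simulate()`,
`residuals()`, `plot()`.

## Preparation pipeline

Fitting runs a fixed, deterministic pipeline:

1. **Binning.** Raw timestamps map to integer bins (`floor(time / bin_width)`);
   several observations of one variable in one bin collapse to the *last
   observed value*. Binning is idempotent and leaves unobserved bins absent.
2. **Patient-level splitting** into train/validation/test (default
   80/10/10), optionally stratified on static attributes by
   largest-remainder allocation within stratum, so no patient contributes to
   both fitting and evaluation.
3. **Two-step outlier filtering** of target values. Step 1 removes values
   outside mean &plusmn; 3 sd, with mean and sd computed on the training split
   only; step 2 recomputes both on the survivors and clips everything
   remaining into the recomputed band. The procedure removes gross noise
   while retaining attenuated extremes. Where the recomputed sd is zero the
   variable is flagged and left unclipped. We center the 3-sd rule on the
   mean (the standard z-score convention); a robust center would be a
   reasonable variant but is not what z-scoring baselines use.
4. **Quantization.** All numeric target values are rounded to the template's
   reporting precision (1 decimal, the granularity of a lab report). This
   makes text serialization lossless: a value travels through
   encode &rarr; generate &rarr; decode without rounding drift, which in turn
   lets a deterministic text backend reproduce the native copy-forward
   baseline *bit for bit* -- the pipeline's sharpest correctness check.
5. **Landmarking.** Each patient record is cut into forecast examples at
   landmark times: the start of each therapy line (`therapy_start`), a fixed
   history window (`fixed_history`, e.g. the first 24 ICU hours), or the
   first visit (`baseline_only`). History is everything at or before the
   landmark -- we deliberately use *all* pre-landmark data rather than a
   truncated window, since the encoder can carry long histories and
   truncation is a token-budget concern, not a modeling one. Examples with
   no observed future target are dropped with accounting.

The baseline value `v0` of a target -- needed both by the copy-forward
reference and by the MASE denominator -- is defined as the last observed
value at or before the landmark. When a target was never observed
pre-landmark, forecasting falls back to the training-split median of that
target's observed future values (flagged), and the patient sample is
excluded from MASE, where an imputed `v0` would make the denominator
arbitrary. Pooling the median over the training examples' *target* values,
rather than over all training observations, keeps the statistic computable
from the training texts alone, so text-channel backends and native
forecasters agree exactly.

## Encoding and decoding

The input template has four sections, each with a fixed header: patient
history (one line per bin, `week -3: hemoglobin=10.4; leukocytes=5.1`, only
observed values), patient information (statics), forecast dates
(`week 1, week 2, ...`), and the instruction fixing the output contract.
Offsets render as `"<unit> <k>"` with the landmark at 0; numbers with one
decimal. The output is a JSON object mapping each target to
`{"week 1": 10.2, ...}` -- during training only the observed future cells,
at prediction time the full target &times; horizon grid.

Decoding is deliberately tolerant: the first balanced, parseable JSON object
anywhere in the generated text is used; prose before or after is ignored;
missing or non-numeric cells are skipped. Every generation is accounted as
`ok`, `partial`, or `failed` -- failures are data, not exceptions, because a
generative model is free to produce garbage and the evaluation must say how
often it does.

Two input perturbations support robustness studies. `inject_misspellings()`
applies `n` independent single-character operations -- adjacent-character
swap ("perturbation", the standard typo model), insertion, deletion,
replacement -- at uniform positions over the *entire* prompt, including
dates, names, and values; insert/replace characters come from ASCII letters
and digits; each operation changes Levenshtein distance by at most 2.
`mask_observations()` removes each history observation independently with a
given probability, on top of the data's own missingness; the truth and the
recorded evaluation constants are never touched. Note that misspellings may
corrupt the instruction section itself; we perturb the full prompt as the
protocol states and accept that as part of the stress.

## Backends

A backend is anything satisfying the two-function contract: `fine_tune()` on
encoded input/target pairs, `generate_text()` sampling `k` completions.

**Echo** is the text-channel copy-forward baseline: it parses the prompt's
own history section and answers, for every schema cell, the last value
mentioned for that variable (training median when absent), as valid JSON.
Its completions are deterministic, so the full pipeline run with it must
equal the native `copy_forward_forecast()` exactly.

**Tiny causal LM** is a small pre-norm transformer (defaults: 1 block,
64-dimensional embeddings, 2 heads, 128-unit ReLU feed-forward, learned
positions, ~0.2M parameters at a typical vocabulary) implemented in
compiled code with manual backpropagation and Adam. Sequences are
`<bos> input target <eos>`; the cross-entropy loss is masked so gradients
flow only from target-text positions (and `<eos>`), the same output-masked
objective used to fine-tune large instruction-tuned models. The tokenizer is
word-level with numeric literals kept as single tokens (a GPT-style leading
space attaches to each token, so concatenation reproduces the text byte for
byte). We chose single-token numbers over character or word-piece splitting
deliberately: at one-decimal precision the value vocabulary is a few hundred
tokens, each forecast cell becomes a *single* categorical emission, and the
per-time-point mean over 30 sampled trajectories approximates the model's
conditional expectation -- which is what makes a model this small learnable
in CPU minutes. Sampling uses temperature 1.0 with top-p 0.9; both are
knobs, and all randomness flows through R's RNG so one seed reproduces
training and generation exactly. Training defaults (10 epochs, learning rate
2e-3, batch 16) were set from the memorization and loss-curve behavior on
synthetic corpora. Over-length pairs are rejected with their index under the
default `"error"` truncation policy, or front-truncated on the input side
under `"truncate"`.

**External adapter** wraps any user-supplied generation function (an API
client for a hosted LLM) in the same contract; no weights ship with the
package, and the conformance tests run against a canned-response double.

## Ensembles, aggregation, and the oracle bound

Each forecast draws `k = 30` trajectories. The final prediction is the
per-cell arithmetic mean of the parsed samples; partial parses contribute
the cells they have. Cells with no parsed sample at all fall back to the
copy-forward value and are flagged -- dropping such patients would make
evaluation denominators incomparable across backends. How malformed
generations among the 30 ought to be handled is genuinely open; this
fallback policy is declared, not inferred.

`oracle_best_trajectory()` selects, with hindsight, the fully parsed sample
with the lowest per-example scaled MAE (per target, mean absolute error over
that target's observed cells divided by its sd, averaged over targets; ties
break to the lowest index). It is a theoretical lower bound on what a
perfect aggregation rule could extract from the ensemble and is reported
alongside the mean aggregate. On a well-calibrated model the mean can beat
the best single draw; the gap between the two is exactly the headroom an
aggregation method could still claim.

Two native reference forecasters frame the backend: copy-forward (last
observed value, the naive bound) and a per-(target, offset) least-squares
model on last value, time since last observation, and static one-hots, with
copy-forward fallback for unfittable cells.

## Evaluation suite

All error metrics use *patient-nested* averaging: the inner mean runs over
one patient sample's `T_i` observed future points, the outer mean over
samples, so a densely observed patient cannot dominate.

* **MAE**, **scaled MAE** (MAE divided by the target's training-split sd
  after outlier filtering -- the primary, cross-variable-comparable score),
  **MASE** (nested MAE over the nested error of always predicting `v0`;
  exactly 1 for the baseline predictor; samples with missing `v0` or zero
  denominator excluded with a count), and **SMAPE** (bounded in \[0, 200\],
  with zero-denominator terms skipped by an indicator).
* **Weighted Spearman**: ranks are computed over the pooled values of one
  target (average ranks on ties) and correlated with per-cell weights
  `1/(n T_i)`. Pooling a single rank function across patients is the literal
  reading of the defining formula; a per-patient variant would be a
  different statistic, and we flag this choice rather than silently pick.
* **Reference-range classification.** Observed values are labeled low /
  normal / high against clinical reference intervals (sex-specific for
  hemoglobin); boundary equality counts as normal -- the defining
  inequalities are strict on both sides, leaving equality undefined, and the
  closed-interval reading is the convention here. Each derived binary task
  is scored by Mann-Whitney ROC AUC with 0.5 tie credit; since only
  predicted *values* exist, ROC scores are signed threshold distances
  (`v_min - pred` for low, `pred - v_max` for high, the minimum of the two
  margins for normal) -- monotone in the prediction and threshold-free. The
  weighted AUC averages the three with class counts as weights. A
  bleeding-risk evaluation is the same machinery with the hemoglobin
  threshold set to 7.5 g/dL; it is a configuration, not a code path.
* **Trend classification.** A point at horizon time `t` is labeled
  decreasing when *every* consecutive change over the lookback window of
  length `s` (default 3 weeks) is strictly downward -- i.e. the `s` pairs
  ending at `t`; increasing symmetrically. Points with `time < s`, or with
  an incomplete window (a missing truth cell inside it), are excluded and
  counted. The baseline value is prepended at time 0 so the earliest
  horizons can have complete windows. The ROC score of a predicted
  trajectory is its worst-case consecutive margin over the window, positive
  exactly when the prediction itself satisfies the strict trend.
* **Distributional fidelity**: the two-sample Kolmogorov-Smirnov distance
  between pooled predicted and observed values per target (computed directly
  on the ECDFs, which is well defined under the heavy ties that one-decimal
  quantization produces).
* **Correlation preservation**: Pearson correlations between each target
  pair on co-observed truth cells, computed once for truths and once for
  predictions; the squared correlation between the two pairwise-correlation
  vectors summarizes whether forecasts respect the cohort's cross-variable
  structure (it needs at least two valid pairs, hence three or more targets).

Significance testing between models is out of scope; reports carry point
estimates and accounting only.

## The synthetic cohort generator

Restricted oncology, ICU and dementia registries cannot ship with a package,
so every stage is exercised against a seeded generator whose structure
mirrors what the method assumes about such data: per-patient baselines and
slopes, shared AR(1) latent factors loaded across variables (planting the
cross-correlations), an ordinal performance-status effect, treatment classes
with opposite post-landmark drifts, Bernoulli thinning to 94.4% missingness
in the default configuration, and one-decimal lab-report rounding. Thinning
is MCAR by default with an optional value-dependent MNAR mode, because
clinical missingness is often informative; the generator exposes both
regimes and claims fidelity to neither. What it does **not** emulate:
disease-specific nonlinear dynamics, informative visit processes (all
variables thin independently), free-text clinical notes, measurement-device
artifacts. Passing tests therefore demonstrate the machinery is correct and
the learning channel works -- not that any real cohort would yield the same
numbers.

The `learnable_cohort_config()` preset defines the package's standing
learnability benchmark and was fixed once, from a predictability argument
rather than from test outcomes: two correlated variables with small baseline
spread (sd 0.4), AR(1) noise sd 0.25, and two therapy classes drifting
&plusmn;0.5 and &#8723;0.3 units/week after the landmark. Copy-forward's
error then grows roughly linearly in the horizon (~1.25 units at week 4 for
the first variable) while the class- and week-conditional residual sd stays
near 0.47, so any model that learns the conditional mean has a wide,
pre-computable margin over the naive baseline. The standing problem sizes --
2,000 patients for the learnability run, 1,000 for correlation recovery, 500
for missingness calibration, 100 for the text-channel equivalence check, 200
random small panels for metric-oracle equivalence -- were chosen as the
smallest sizes at which the corresponding Monte-Carlo error is comfortably
below the property being asserted.

## Numerical and degenerate-input conventions

Half-away-from-zero rounding everywhere a number meets text, so stored and
rendered values agree; zero-variance targets flag and skip clipping;
AUC tasks missing a class report `NA` and drop out of weighted means;
all-tied scores give 0.5 by rank construction; ensembles whose every draw
fails still evaluate (via flagged fallback); oracle selection over an
ensemble with no fully parsed draw is an error at the operation level and a
counted skip at the pipeline level; stage seeds derive from one global seed
by a fixed hash, all below 2^31.

## Limitations

The tiny backend is a mechanism demonstration, not a clinical model: it
learns conditional value distributions at one-decimal resolution from
hundreds of training texts, and its skill claim is specific to the planted
dynamics of the synthetic benchmark. Real deployments would slot a large
instruction-tuned model into the external adapter, where fine-tuning happens
outside this package. Trend AUCs are sensitive to the truth-window
completeness rule under heavy sparsity (many excluded points); the
correlation-preservation summary needs three or more targets; and the
chatbot-style explanation parsing extracts variable mentions only -- it does
not assess whether an explanation is true.
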