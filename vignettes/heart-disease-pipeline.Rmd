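---
title: "Methods: a hybrid-selection, cluster-resampled, metaheuristic-trained heart-disease classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid-selection, cluster-resampled, metaheuristic-trained heart-disease classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the data model

`hdpm` implements a complete clinical risk-prediction pipeline for
tabular heart-disease records in the classic UCI 14-attribute dialect:
thirteen predictors (age, sex, chest-pain category, resting blood
pressure, serum cholesterol, fasting blood sugar, resting ECG, maximum
heart rate, exercise angina, ST depression, ST slope, fluoroscopy
vessel count, thallium result) plus a graded outcome `num` in 0–4,
binarized to absence (0) versus presence (1–4) of disease. Missing
values are encoded `?` in files and `NA` in memory; the outcome may
never be missing. A reference cohort of this shape has 303 records with
a 164:139 class balance, which the synthetic generator reproduces
exactly by deterministic label allocation.

The pipeline has five modelling stages, each usable on its own:

1. **Preprocessing** — cohort-based imputation, exact-duplicate
   removal, chest-pain segregation, and z-score standardization.
2. **Feature selection** — a genetic algorithm (GA) over feature
   bitmasks refined by recursive feature elimination (RFE).
3. **USCOM resampling** — under-sample the majority class, cluster the
   minority, split 8:1:1 per group, and SMOTE the merged training set
   to exact class balance.
4. **Classification** — a dense multilayer network with Gaussian
   hidden activations `exp(-x^2)` and a linear output unit, trained by
   online backpropagation.
5. **AEHOM** — an adaptive elephant-herd metaheuristic that searches
   network weight space and interleaves with backprop refinement.

## Preprocessing choices

The imputation rule fills a missing field from "cohort peers":
patients agreeing on the patient's age category, cholesterol level and
blood pressure level. No numeric similarity rule accompanies that idea
in the source narrative, so it is operationalized as: same age bin
(default width 10 years) and same sample quartile of `chol` and
`trestbps`, with a peer qualifying when at least a `match_quorum`
fraction (default 0.5) of the similarity fields agree. Categorical
fields take the cohort mode, continuous fields the cohort mean, with a
global fallback when no peer observes the field. Observed values are
never altered, and a field missing in every record is an error rather
than a silent zero-fill.

Standardization uses the sample standard deviation (n − 1 denominator);
this is stated because bit-level reproducibility of the scaler matters
for the seeded determinism contract. When the pipeline is
cross-validated, the scaler (and every other stage) is fit inside the
training fold only.

## Feature selection

Each GA genome is a 13-bit retention mask; its fitness is the 3-fold
cross-validated mean squared error of a ridge regression of the binary
label on the masked columns (folds seeded once per search, so fitness
is a pure function of the mask). A closed-form ridge fit keeps the
~1,500 evaluations of a default search affordable; a fitness cache
avoids re-scoring repeated masks. Defaults follow the published search
protocol: 18 generations × 80 genomes, 40 elites + 40 fresh randoms, 5%
single-point crossover, 0.05 per-bit mutation. Because elites and
randoms exhaust the population, the crossover and mutation operators
act on the elite mating pool in place; the best genome ever seen is
archived separately, which is why the reported history is
non-increasing even though individual elites can be perturbed.

RFE then refines the GA winner: ridge coefficients on internally
standardized columns are the importance scores, and the lowest-ranked
feature is dropped per round until `n_keep` remain. The hybrid runs
GA-then-RFE (global search, then local refinement); the result is by
construction a subset of the GA winner. The pipeline default clamps
`n_keep` to the achieved GA subset size (`clamp_n_keep = TRUE`),
because the subset size is stochastic inside cross-validation folds;
strict mode raises a stage-named configuration error instead.

## USCOM resampling

The resampler (a) randomly retains a fraction of the majority class
(default 2/3, the imbalance ratio reported for the critical-care
reference cohort; it is configuration because other cohorts differ),
(b) clusters the minority class so every minority subgroup contributes
rows to training, validation and test, (c) splits each group 8:1:1
(test and validation get `max(1, round(0.1 n))` rows each, training the
remainder — fixed so small-n counts are reproducible, e.g. 7 → 5/1/1),
and (d) SMOTE-balances the merged training set. Under-sampling can flip
which class is rarer in the merged training set, so step (d)
over-samples whichever class is smaller there; the balance law (exactly
equal training counts, synthetic rows only in training) then holds for
every input. Clusters with fewer than 3 rows go entirely to training.

The cluster count comes from an SSE elbow: k-means (Lloyd, seeded, SSE
per the within-cluster squared-error definition) is fit for each
candidate K, and the chosen K is the one after which the SSE
improvement — measured relative to the SSE at the smallest candidate —
first drops below `elbow_threshold` (default 0.10). Normalizing by the
initial SSE rather than the previous one makes the rule scale-free and
insensitive to the slow 1/K decay that plain k-means exhibits even on
unclustered data; a degenerate point-mass cloud yields the smallest
candidate, and if the curve never flattens the largest candidate is
used.

SMOTE neighbors are found on internally standardized columns (raw
Euclidean distance would be dominated by cholesterol and blood-pressure
magnitudes) while interpolation happens on the original scales, so
every synthetic point lies on the segment between its seed and a
k-nearest minority neighbor.

## The classifier and its training

The network is dense (the printed layer equations contain no
convolutional structure): hidden units compute `C = exp(-M^2)` of their
bias-plus-weighted-sum `M`, and the output unit is linear with the 0/1
decision made downstream at a threshold (default 0.5, ties to 1). The
Gaussian activation makes hidden units radial-basis-like bump detectors
on projections of the input; its derivative `-2u exp(-u^2)` vanishes at
the peak, which backpropagation uses as the hidden error signal.
Weights start uniform on `[-init_scale, init_scale]` (default 0.5) and
updates are online (per sample, freshly shuffled each epoch) with the
additive delta rule `alpha * k * input` (default `alpha` 0.05,
60 epochs in the pipeline). Non-finite loss aborts with the epoch
number rather than continuing silently.

AEHOM searches the flattened weight vector (layer-major, weights then
biases per layer) on a `[-1, 1]` box. Per generation: clan members step
toward their matriarch by `c (best - p) r` with per-dimension uniform
`r` (default `c` 0.5); the matriarch moves to `l ×` the clan center
(default `l` 0.1); the `n_worst` worst members of each clan are
re-scattered uniformly within bounds; the bests of randomly paired
clans exchange the fixed gene segment `[floor(L/3), floor(L/3) +
floor(L/2))` by two-point crossover (skipped below 6 dimensions, where
the cut formula collapses); and genes mutate to fresh uniform draws at
rate 0.05. Fitness is training-set MSE of the decoded network
(minimization; the narrative's "higher fitness" is inverted
accordingly), every operator clips to bounds, and the best-ever
position is archived, so the history is non-increasing by construction.
The published form of the separation operator is syntactically garbled;
the standard form `P_min + (P_max - P_min) k` is used, and the
fractional crossover cut points are floored because gene indices must
be integral.

The pipeline default interleaves 1 backprop epoch after every 5 AEHOM
generations (20 generations, 3 clans × 10 elephants), re-inserting the
refined, bounds-clipped parameters over the worst elephant; the final
best network then receives the configured backprop epochs. With zero
generations the procedure reduces exactly to pure backprop from the
seeded random initialization, which the tests exploit as an oracle.

## Evaluation protocol

Metrics are the standard six (accuracy, precision, TPR/sensitivity,
FPR, specificity, F-score) with disease-present as the positive class;
0/0 ratios are reported as 0 and flagged. Cross-validation is
stratified (class proportions preserved per fold, k default 10) and all
resampling happens inside each training fold — applying SMOTE before
splitting would leak interpolated copies of test rows into training.
Both protocols of the source narrative are available: the USCOM 8:1:1
split (via `run_mlhdpm()`) and k-fold CV (via `mlhdpm_cv()`).

## What the synthetic generator does and does not emulate

`gen_tabular()` reproduces the schema (legal categorical supports,
realistic continuous marginals, graded outcome, exact class-ratio
allocation, MCAR `?` missingness) and plants a known signal:
`n_informative` continuous predictors shifted between classes by
`effect_size` standard deviations (maximum heart rate shifts downward
with disease, the others upward). Within-class distributions are
Gaussian and predictors are independent — the simplest structure that
exercises scaling, SMOTE geometry and selection recovery. It does not
mimic real correlation structure, categorical-outcome dependence, or
informative missingness; passing the recovery benchmarks therefore
demonstrates that the machinery works as specified, not that the
headline accuracies on any real cohort would be reproduced. The
signal-feature module is exercised by `gen_rr_series()` (truncated
Gaussian RR intervals with controlled mean and variability); how such
device features would join the 13 tabular predictors is not defined by
the source narrative, so they are exposed as optional extra columns
rather than wired into the default pipeline.

Two printed formulas are dimensionally anomalous and are provided in
both conventions behind mode flags, defaulting to the corrected form:
the grid entropy (ratio form `sum(P / log P)`, always negative, versus
Shannon `-sum(P log P)`, natural log in both) and the successive-
difference RMS (unsquared form `sqrt(sum(diff) / (M - 1))`, undefined
for negative sums, versus the standard RMSSD). Sums over successive RR
differences run over the M − 1 valid adjacent pairs, since the first
term of the printed indexing is undefined. Zero samples count as "no
change" in the zero-crossing rate (strict sign change).

## Problem sizes and reproducibility

The package's benchmark conditions, used by the test suite and the
acceptance script alike, are: selection recovery on n = 300 with 2
informative of 10 features at effect size 2.0; optimizer convergence on
the 5-D sphere with 3 clans × 10 elephants over 100 generations; and
the end-to-end benchmark on n = 500 records of the 13-column schema at
the 164:139 balance with 4 informative predictors at effect size 2.0
(joint class separation ≈ 4 sd, Bayes accuracy ≈ 0.98, so the 0.95
cross-validated bar is attainable but not trivial). One global seed
derives every stage seed by a fixed counter scheme; identical
configurations reproduce reports byte-identically apart from timings.

```{r}
library(hdpm)
cfg <- mlhdpm_config(seed = 1, synthetic = tabular_spec(
  n = 500, n_informative = 4, effect_size = 2, seed = 1))
report <- run_mlhdpm(cfg)
report$metrics$test
```

## Known limitations

- The base learner for selection is a ridge regression; strongly
  non-additive signals could be under-ranked even though the downstream
  network could represent them.
- The matriarch update `l × center` contracts toward the origin; for
  weight search on standardized inputs this acts as mild shrinkage, but
  on problems whose optimum is far from the origin a larger `l` is
  advisable. Bounds clipping is the guard.
- Multi-cohort merging (the four classic heart-disease databases) is
  out of scope; the reader/writer handles one table at a time.
- No ROC/AUC machinery: the evaluation mirrors the six reported
  threshold metrics.
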