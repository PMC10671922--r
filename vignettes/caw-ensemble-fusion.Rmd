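---
title: "Consensus-adaptive weighting: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-adaptive weighting: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cawfuse)
```

## The problem

A computer-aided detection (CAD) pipeline for screening mammography rarely
relies on a single classifier. Several convolutional networks trained on
the same images make partly independent errors, and fusing their outputs
at the decision level is a cheap way to buy accuracy without retraining
anything. cawfuse implements one such fusion family — consensus-adaptive
weighting (CAW) — together with the evaluation harness and the
class-imbalance utilities that a screening dataset forces on you.

The package never touches images. Its unit of data is the *predictions
table*: one row per sample, a binary `label` (1 = malignant/positive), and
one column per base model holding that model's predicted probability of
the positive class. Anything that produces such a table — five CNNs, a
random forest and two gradient boosters, whatever — can be fused.

## The model

Let $X_i$ be base model $i$'s validation F2 score. The F2 score is the
$\beta = 2$ member of the F$_\beta$ family,

$$
F_\beta = \frac{(1+\beta^2)\,TP}{(1+\beta^2)\,TP + FP + \beta^2\,FN},
\qquad
F_2 = \frac{TP}{TP + 0.2\,FP + 0.8\,FN},
$$

which weights recall four times as heavily as precision. In screening, a
missed cancer is far costlier than a recalled healthy patient, so the
score a model is *weighted by* should prize recall; that is the single
most consequential modelling commitment in the package, and `beta` is a
parameter everywhere if your cost ratio differs.

The fusion weights are a power transform of the scores:

$$
w_i = \frac{X_i^{\,C}}{\sum_j X_j^{\,C}}.
$$

* $C = 1$ (**V1**) is plain score-proportional weighting.
* $C > 1$ (**V2**) sharpens the weights toward the better models; as
  $C \to \infty$ the weights approach one-hot on the best model, and
  $C < 1$ flattens them toward uniform. Because the transform is applied
  to scores on *any* common scale, percentages and fractions give
  identical weights (a property the test suite checks).

Fusion itself is *soft*: the ensemble probability is the weighted
arithmetic mean $\sum_i w_i\,p_{si}$ of the model probabilities,
thresholded at 0.5 (configurable) into a label. The competing baseline,
majority vote, thresholds each model first and lets the binary votes
decide; on an exact tie the positive class wins by default, again the
recall-first choice. Soft fusion preserves each model's confidence, which
is precisely the information majority voting throws away.

### Choosing C

`search_c()` selects the exponent by exhaustive search over an inclusive
grid, by default $0.5$ to $20$ in steps of $0.1$ (196 points), built by
integer stepping so repeated floating-point addition cannot drift off the
intended values. The objective is the **mean out-of-fold fused F2**: for
each candidate $C$ and each cross-validation fold, weights come from that
fold's validation scores, that fold's validation predictions are fused
and scored, and the fold scores are averaged. Ties are broken toward the
*smallest* $C$ — the least-sharpened, most conservative weighting. Both
choices (objective and tie-break) were genuinely open design decisions;
the objective is the natural reading of "search across all
cross-validation subsets", and the conservative tie-break avoids
committing to aggressive sharpening that the data cannot distinguish
from a milder one.

Weights are computed in the log domain (a softmax over $C\log X_i$), so
percent-scale scores raised to the 20th power — $93.89^{20} \approx
3\times10^{39}$ — cost no precision and cannot overflow.

## The harness

`run_cv()` mirrors the standard protocol: an 80/20 stratified holdout
(`train_test_split()`) if you want one, then stratified $k$-fold
cross-validation (default $k = 4$) on the rest. Per fold it scores every
model on the fold's validation samples, derives V1 weights, runs the C
search across all folds once, derives V2 weights at the selected $C$, and
scores majority vote, V1 and V2 fusion on the fold. Results are reported
as mean ± sample standard deviation across folds on the percent scale,
plus three derived statistics (`summarize_methods()`): the mean over all
methods, V2's gain over the best base model, and V2's gain over V1.

Two deliberate choices:

* **Stratified folds by default.** At 14% prevalence an unstratified
  4-fold split can easily leave a validation fold with no positives,
  making F2 undefined; `run_cv()` refuses such folds with advice rather
  than silently scoring them.
* **Per-fold weights vs deployed weights.** Fold-level scores use weights
  from that fold's own validation scores; the *deployable* weight vectors
  in the report are computed from fold-averaged scores at the selected
  $C$. The protocol's train→weight→test flow admits either reading; using
  per-fold weights inside CV and averaged scores for deployment keeps the
  fold scores honest while giving a single stable weight vector to ship.
* **C is selected on validation folds only**, never on held-out test
  data.

## Data-shaping utilities

Three label-level procedures cover the common imbalance regimes, using
the scales of public mammography collections as their reference points:

* `undersample_balance()` — when the majority class is huge (48,600
  negatives against 7,290 positives), keep every minority sample and a
  seeded uniform subset of the majority, yielding exactly
  $2\times$ the minority count (14,580).
* `make_balanced_batches()` — when the dataset is too small to discard
  anything, emit training batches (default size 32) containing exactly
  half of each class. Per epoch each class is consumed as concatenated
  random permutations, so no sample of a class repeats before the class
  is exhausted; the smaller class then recycles.
* `plan_augmentation()` — when even that is not enough (410 images, 100
  malignant), compute how many augmented copies per class reach a
  balanced target (e.g. 4,000 total, originals included), spreading
  copies across originals so per-original counts differ by at most one.
  The plan is a count contract for an external augmenter; cawfuse
  deliberately executes no image transforms.

## The synthetic generator

`simulate_predictions()` stands in for the trained backbones. Each sample
carries a latent signal $s = \pm 1$ and a shared noise draw $u$; model
$m$ sees

$$
z_{sm} = d_m s + \sigma\!\left(\sqrt{\rho}\,u +
\sqrt{1-\rho}\,e_{sm}\right),\qquad p_{sm} = \mathrm{logit}^{-1}(z_{sm}),
$$

with independent $e_{sm}$. The gain $d_m$ sets model $m$'s
discrimination, $\rho$ the fraction of noise variance shared across
models (one parameter tuning the inter-model score correlation — the
reason this construction was chosen), and the logistic link keeps scores
in $(0,1)$; a probit link would serve equally.

Defaults are fixed once and emulate a screening ensemble: five models
with unequal, overlapping gains $(2.2, 1.8, 1.9, 1.6, 1.3)$, substantial
error correlation $\rho = 0.5$ (the models saw the same images), unit
noise, and 14% prevalence. The generator reproduces the *structural*
features that matter to fusion — unequal skill, correlated errors, class
imbalance — but not the error anatomy of real CNNs on real mammograms:
no difficulty clustering by lesion type, no calibration pathologies, no
augmentation artefacts. Tests passing on synthetic data therefore
validate the fusion machinery and its invariants, not clinical
performance.

Its calibration extremes are tested directly: zero gains give AUC
$\approx 0.5$ (checked against an independent ROC implementation at
$n = 20{,}000$), overwhelming gain saturates F2 at 1, and $\rho = 1$
with equal gains collapses all columns to one model, at which point
fusion provably cannot help.

## Numerical and degenerate-input policy

* Undefined F2 ($TP = FP = FN = 0$) returns `zero_division` (default 0)
  with a warning: an all-negative prediction on an all-negative fold
  demonstrates no positive-class skill.
* All-zero score vectors are an error, not a uniform weight: they mean no
  model found a single true positive, and any weighting would be
  arbitrary.
* Fused probabilities are clamped to $[0,1]$ against floating-point dot
  product overshoot; convexity makes the mathematical value bounded
  already.
* Scores are handled internally on the $[0,1]$ scale; the percent scale
  is a reporting convention (weights are scale-invariant either way).

## Worked example

```{r example, eval = FALSE}
library(cawfuse)

preds <- simulate_predictions(n_samples = 2000, seed = 11)
fit <- run_cv(preds, k = 4, seed = 11)
tidy(fit)      # per-method F2, mean ± sd across folds (%)
glance(fit)    # selected C and derived summary statistics
autoplot(fit)  # method comparison; autoplot(fit$c_search) for the C curve
```

The examples and tests deliberately use moderate sizes (hundreds to a
few thousand samples; 20,000 for the Monte-Carlo sanity checks) — large
enough for the stochastic properties to stabilise, small enough that the
full suite runs in well under a minute on one CPU.

## Known limitations

* The fusion rule is the weighted arithmetic mean of probabilities; the
  weighting family does not cover stacking, calibration, or learned
  (meta-model) combination, and `search_c()` is exhaustive rather than
  gradient-based or Bayesian by design — the grid is small and the
  objective is piecewise constant in $C$.
* $C$ selected on the same folds that produce the fold scores gives a
  mildly optimistic V2 estimate; nested CV would remove the bias at 4–5×
  the cost and is out of scope.
* F2 standard deviations of real trained backbones across folds (a few
  tenths of a percent) reflect the networks' training variance, which the
  synthetic generator does not attempt to match; reported standard
  deviations on synthetic data are typically larger.
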