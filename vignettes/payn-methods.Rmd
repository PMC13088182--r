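---
title: "Mining reliable negatives from positives-only reaction data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining reliable negatives from positives-only reaction data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(payn)
```

## The problem

Published synthetic-chemistry data is censored: low-yielding and failed
reactions rarely make it into papers. A regression model trained on
such data learns the landscape of successes but has no concept of
failure, which is fatal for prospective use — the model cannot warn you
off a doomed substrate/ligand/base combination it has never seen the
likes of. High-throughput experimentation (HTE) campaigns are the
exception (every well is recorded, success or not), but they are
expensive and cover small, deliberately chosen slices of chemical
space.

`payn` treats the censored setting as positive-unlabeled (PU)
learning. The observed label `s` says only "this reaction was
reported"; the latent label `y` says whether it actually works (here:
yield strictly above 20%). The package simulates the censoring process
on fully labeled ground truth, mines reliable negatives (RN) back out
of the unlabeled pool, and measures how much predictive performance the
recovered negatives restore.

## Assumptions, stated plainly

* **SCAR** (selected completely at random): reported positives are a
  uniform random sample of all positives, so the labeling probability
  `c = p(s=1|y=1)` is a constant and `p(s=1|x) = c · p(y=1|x)`. The
  bias simulator enforces SCAR *by construction* — the uniform draw
  that decides which records are "reported" never looks at features.
  Real literature data also carries selection bias (chemists choose
  substrates likely to work); that is a different censoring mechanism
  and is deliberately not simulated here.
* **Separability / smoothness**: positives and negatives must be
  distinguishable in feature space, and similar reactions must behave
  similarly. Both the spy threshold and the mean-score label-frequency
  estimator degrade gracefully, but measurably, as class overlap grows
  (see the `"overlapping"` preset).

## The spy procedure and its numerical choices

Given a PU data set (`P`, `U`):

1. `inject_spies()` conceals `round(spy_rate · |P|)` random positives
   in `U`.
2. `fit_pu_classifier()` trains a gradient-boosted tree ensemble
   (logistic objective) on reduced-`P` vs spiked-`U`.
3. `compute_spy_threshold()` sets `t_spies` to the `k`-th smallest spy
   score with `k = ⌊tolerance · n_spies⌋`.
4. `extract_reliable_negatives()` labels `score ≤ t_spies` as RN, the
   rest undecisive.

Choices that matter and why:

* **Lower empirical quantile, no interpolation.** With
  `k = ⌊tolerance · n⌋` and the `k`-th order statistic, exactly
  `n − k ≥ (1 − tolerance) · n` spies score strictly above the
  threshold; an interpolated quantile would break that guarantee. At
  `tolerance = 0` the threshold is 0: no spy may be sacrificed, and
  only records the classifier scores at exactly zero can become RN.
* **Boundary inclusive.** RN membership uses `≤ t_spies`; a spy tied
  with the threshold counts as misclassified. Ties are vanishingly
  rare with tree-ensemble scores but the convention is fixed so results
  are reproducible to the byte.
* **Raw probability scores.** Spies and unlabeled records are scored
  by the same model on the same scale, so no per-fold normalization is
  applied anywhere in the decision path.
* **Single pass.** Some PU variants retrain on the extracted RN;
  `payn` does not — the RN definition above is the whole procedure.
* **Determinism.** The booster runs single-threaded with all
  randomness derived from explicit seeds; a fixed (data, seed,
  parameters) triple reproduces every artifact byte-for-byte.
  `derive_seed()` splits the one user-facing seed into independent
  per-stage seeds so that, e.g., changing the spy draw does not
  perturb the fold assignment.

## Label-frequency estimation

`estimate_label_frequency()` implements the classical mean-score
estimator: the average classifier score over held-out known positives
estimates `c`. Two practical points the implementation enforces:

* the holdout must be a uniform split of `P ∪ U`. Holding out
  positives only (a tempting shortcut) shrinks the labeled share of
  the training mixture and biases the estimate downward by roughly
  `|holdout| / |P ∪ U|` — an error we measured at ~0.1 during
  development of the cross-fitted variant;
* `estimate_label_frequency_cv()` therefore cross-fits: 5 uniform
  folds, each record scored by a model that never saw it, all labeled
  positives averaged. This uses every positive instead of a 20%
  holdout and roughly halves the estimator's spread.

The estimator inherits a small downward bias from borderline
positives: records with `p(y=1|x) < 1` (yields within noise reach of
the 20% cutoff) contribute `c · p(y=1|x) < c` to the mean. At the
default yield noise of 2 percentage points this bias is below 0.01;
at noise 5 it reaches ~0.02 on the separable scenario. It is a
property of the estimator, not of the implementation.

## The synthetic HTE generator

`generate_hte_dataset()` emulates the structure of combinatorial HTE
plates:

* every role (substrate, ligand, base, …) has a fixed component
  alphabet; each component draws one latent vector, shared by every
  reaction containing it — this reproduces the blocked correlation
  structure that makes HTE grids easier to learn than random samples;
* components belong to a "reactive" or "unreactive" cluster whose
  centers sit `separability` apart on the first latent coordinate;
  the remaining `latent_dim − 1` coordinates are pure distractors;
* a reaction's latent score is the sum of its components' first
  coordinates; the noise-free yield is `100 · plogis(score + b)` with
  the intercept `b` bisected so the noise-free positive rate
  (yield > 20) matches `target_positive_rate`. Because the empirical
  rate moves in steps of `1/n`, the match is accepted within
  `max(0.005, 1/n)` and the nearer of the two flanking achievable
  rates is taken;
* Gaussian noise (`yield_noise_sd`, default 2 percentage points —
  replicate-level reproducibility of automated plates) is added and
  the result clipped to `[0, 100]`. The returned oracle is the exact
  success probability `P(yield > 20 | x)` under this model.

What the generator does **not** emulate: mechanistic chemistry
(activation barriers, incompatible functional groups), selection bias
in component choice, heteroscedastic noise at high yields, or any
relation between a component's latent vector and its structure in the
optional SMILES mode (the SMILES exist purely to exercise the
fingerprint code path). A pipeline that passes every test here is
therefore validated for its *statistical* behavior under SCAR
censoring — not certified to reach any particular accuracy on real
HTE chemistry.

Scenario presets freeze the study conditions used throughout the test
suite: 3 roles × 13 components (2197 combinations, 2000 kept),
`separable` (separability 4, positive rate 0.4), `overlapping`
(1, 0.4), `rare_positive` (2, 0.25). The label-frequency check runs a
larger draw (18 components per role, 5000 records) so the Monte-Carlo
error on the mean score is small against the ±0.05 band.

## Tunable parameters

| parameter | default | units | why this default |
|---|---|---|---|
| `yield_threshold_pct` | 20 | % yield | the conventional success cutoff for these data sets; strict `>` |
| `pu_ratio` | 0.5 | fraction | half the grid "run and reported" is the mid-point scenario; `c = pu_ratio` under SCAR |
| `spy_rate` | 0.1 | fraction of `P` | large enough for a stable spy score distribution, small enough not to starve training |
| `spy_tolerance` | 0.05 | fraction | 95% of spies must stay above the threshold; the worked value throughout |
| `rn_yield_pct` | 0 | % yield | RN are treated as failed reactions; configurable up to the threshold |
| `depth` / `learning_rate` / `iterations` | 6 / 0.1 / 300 | — | standard moderate-capacity boosting; calibration of the logistic scores matters more than raw accuracy here |
| `n_folds` / `validation_fraction` | 5 / 0.10 | — | five-fold CV with a 10% validation split for tuning |
| `hpo_trials` | 0 | trials | tuning off by default so benchmarks are deterministic |

When `hpo_trials > 0`, hyperparameters are tuned by seeded random
search over depth 3–10, learning rate log-uniform on `[1e-3, 0.3]`,
and 100–1000 iterations, selected by validation MAE (regressors) or
log-loss (classifier). Random search was chosen over sequential
model-based optimization as the package's own trade-off: it is
dependency-free, embarrassingly reproducible under a single seed, and
for a 3-dimensional space its efficiency penalty is modest; the
search space and selection objective are the contract, the optimizer
is swappable.

## Benchmark design

`run_benchmark_cv()` holds each test fold out *before* any PU
transformation — test folds keep their natural class mix and never
touch spy training, threshold derivation, RN extraction, or tuning.
On the training folds the full pipeline runs from scratch, then three
regressors (MAE objective, predictions clipped to `[0, 100]`) are fit
on identical splits: fully labeled, positives-only, and RN-augmented.
Reported MAEs are averaged over folds ± sd, and the gap-closed
percentage is computed from the mean MAEs, unclipped (values above 100
or below 0 are informative). Folds whose PU draw contains no positive
are skipped with a warning and recorded; an all-fold failure is an
error, never a silent zero.

Two conventions worth flagging as decisions:

* **Stripped negatives are discarded, not pooled into `U`** — they
  model failures that were run but never published and are simply
  lost. Pooling them would change `c` and overstate recall.
* **Spies return to the positive pool for regression** — their true
  yields are known, there is no reason to waste them.
* **Empty-RN folds report precision as missing** (0/0), not 0 or 1,
  and aggregation skips them.

## Known limitations

* The RN yield imputation (constant 0%) is crude; on data where
  failures cluster at 5–15% yield it will bias the augmented regressor
  low near the decision boundary.
* The mean-score estimator of `c` is only as good as the classifier's
  calibration; heavily overlapping classes (separability ≲ 1) push it
  visibly below the true value.
* The false-positive rate is reported as the latent-positives-in-RN
  cell as a fraction of the whole unlabeled pool (the confusion-
  partition convention); readers expecting a fraction of `|RN|` should
  use `1 − negative_precision` instead.
* SMILES featurization requires `ChemmineOB`; the numeric passthrough
  path has no chemistry dependency at all.
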