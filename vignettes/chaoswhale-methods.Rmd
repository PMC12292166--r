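---
title: "Dynamic chaotic whale optimization and progressive ensemble training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic chaotic whale optimization and progressive ensemble training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaoswhale)
```

## What this package computes

`chaoswhale` implements the optimization and training machinery of a
brain-tumor MRI classification workflow in a form that can be exercised
end-to-end on synthetic data: the Whale Optimization Algorithm (WOA) and its
chaotic variants, a mixed hyperparameter search space for a convolutional
classifier head, an image-size-adaptive learning-rate scheduler, a
progressive image-resizing training orchestrator, classifier ensemble
fusion, and the usual classification metrics. Full-scale training of a deep
backbone on real MRI is deliberately out of scope; the package treats the
trainer as a pluggable contract and ships a small deterministic reference
trainer so that the orchestration, chaining, and fusion logic are all
testable at desk scale.

## The whale optimizer family

WOA is a population metaheuristic over a box-bounded real vector space,
minimizing a user-supplied objective (here: fitness is a loss, so lower is
better; maximization is handled by negating at the boundary). Each of the
`n` agents ("whales") at iteration `t` moves by one of three rules,
selected per agent:

* **Encircling** (exploitation): `D = |C ∘ X* − X|`, `X ← X* − A ∘ D`,
  where `X*` is the best position found so far.
* **Spiral** (exploitation): `X ← |X* − X| · e^{bl} · cos(2πl) + X*` with
  `l ~ U(−1, 1)` and spiral shape constant `b` (default 1).
* **Exploration**: as encircling but around a uniformly chosen population
  member `X_rand` instead of the leader.

The coefficients are `A = 2a·r − a` and `C = 2r` with `r ~ U(0, 1)` and a
linearly shrinking `a = 2(1 − t/T)`. A draw `p ~ U(0, 1)` picks the spiral
when `p ≥ 0.5`; otherwise the magnitude of a scalar `A` draw picks
encircling (`|A| < 1`) or exploration (`|A| ≥ 1`).

Several details of this scheme are under-determined in the common
pseudocode, and the package fixes them explicitly:

* **Branch scalar vs. update vector.** One scalar `r` per agent drives the
  `|A|` branch test; an independent per-dimension `r` vector drives the
  position arithmetic. Both granularities exist in published
  implementations; this choice is documented and frozen, and the unit tests
  pin the exact draw order (`r` scalar, `p`, `l`, `r` vector, random index).
* **In-place updates.** Agents move sequentially within an iteration, and
  `X_rand` is drawn from the current (partially updated) population, with
  self-selection allowed. The leader is held fixed during the loop and
  updated only after all fitness values are recomputed.
* **Elitism and ties.** The leader is replaced only on strictly better
  fitness, so the best-so-far trace is non-increasing by construction.
* **Bounds.** Positions are amended by clipping (the simplest reading of
  "amend"), which is idempotent.
* **Non-finite objectives** are recorded as `+Inf` with a warning and can
  never become the leader.

### Chaotic coefficients (CWOA)

The chaotic variant replaces the uniform `r` draws in the coefficient
equations with a chaotic sequence; `p`, `l`, and the random-agent index
stay RNG-driven. This substitution point is the canonical one in the
chaotic-WOA literature; it is configurable in the sense that the sampler
interface is public. Two maps are built in:

* logistic: `x ← r·x·(1 − x)`, control parameter `r = 4` (full chaos);
* sine: `x ← sin(πx)`.

The chaotic value is advanced **once per iteration** and shared across
agents, matching the placement of the "update the chaotic number" step in
the variant's loop structure (an alternative per-agent stream would change
the algorithm; it is not provided). Seeds in `{0, 0.25, 0.5, 0.75, 1}`
(logistic) or `{0, 1}` (sine) are fixed or eventually-fixed points that
collapse the sequence, so the seed screen rejects them; the default seeding
draws uniformly from `(0.01, 0.99)` out of the run RNG. A registry hook
allows additional maps, which the tests use to pin the stream to a
constant and recover plain WOA behavior exactly.

### Dynamic map switching (DCWOA)

The dynamic variant tracks a stagnation counter: an iteration whose best
fitness fails to improve **strictly** on the best previously seen
increments it; improvement resets it. When the counter exceeds the
threshold (default 5, i.e. the switch fires on the 6th consecutive stagnant
iteration) the active map toggles between logistic and sine, the switch
iteration is logged, and the counter resets. Two ambiguities were settled
as follows:

* The printed rule `counter > 5` and the prose "five consecutive
  iterations" are off by one; the implementation uses `counter >
  threshold` with a configurable threshold defaulting to 5, so the first
  switch fires on the 6th stagnant iteration.
* Only a logistic-to-sine switch is printed, but the method is described as
  *alternating* between the maps, so the default is a toggle; a strict
  one-way mode is available (`switch_mode = "one_way"`).
* The chaotic sequence position is **not** reset at a switch: the current
  value feeds the new map.

With a strictly improving trace the dynamic variant never switches and is
bit-identical to the static chaotic variant at the same seed — one of the
acceptance-style tests asserts exactly this.

## The mixed hyperparameter space

The tuning target is five-dimensional: learning rate (log-continuous over
`[1e-4, 1e-2]`), dropout (continuous `[0.2, 0.5]`), optimizer (Adam,
RMSprop, AdamW, Adamax, Nadam), activation (ReLU, Tanh, Sigmoid), and
first-dense-layer neurons (integer `[256, 1024]`; the alternative lower bound 254 that
circulates for this space is accepted via `neuron_low = 254`).
The optimizer works on real vectors, so a codec bridges the two views:

* learning rate is searched as `log10(lr)` — the range spans two decades
  and a linear search would waste most of its resolution at the top;
* integers round to nearest with ties away from zero, then clip;
* categorical dimensions embed as the interval `[0, K)`: decoding is
  floor-and-clip, encoding maps cell `k` to its midpoint `k + 0.5`. This
  is the simplest order-preserving embedding and makes
  `decode ∘ encode` the identity on valid settings while
  `encode ∘ decode` is an idempotent projection onto cell midpoints.

Decoding is total: any real vector decodes to an in-space setting, so the
optimizer needs no constraint handling beyond its own box. The default
budget of `tune_hyperparams()` is population 10 and 20 iterations.

A separable analytic surrogate (`surrogate_objective()`) stands in for the
real training loss in tests: squared log-learning-rate and dropout
distances, 0.5 penalties for each wrong categorical, and a scaled squared
neuron distance, with its unique zero at a configurable target. An
exhaustive grid oracle in the test suite confirms the minimizer, and a
recovery experiment over 20 seeds checks that the tuner finds both
categorical values and the learning rate within 0.3 decades at that
default budget.

## The learning-rate scheduler

Progressive training revisits the data at sizes 100, 128, 244, 256 and
299 px. The stage learning rate is

&alpha;&prime; = clamp(&alpha; · &beta;(S)^(S/S0), 0.1&alpha;, 10&alpha;)

with the scaling table `β = {100: 1.0, 128: 1.05, 244: 1.1, 256: 1.15,
299: 1.2}` and `β = 1` for unscheduled sizes. The reference size `S0` is a free
parameter of the rule; the package fixes `S0 = 100` — the smallest
scheduled size — so the first stage trains exactly at the base rate, and
exposes it in `scheduler_config()`. With the defaults the rule is
strictly increasing across the five scheduled sizes (larger images get
larger rates), and the clamp guarantees `α′ ∈ [0.1α, 10α]` for any table;
a randomized test sweeps 10^5 draws of `(α, S, β-table)` against the
clamp. The rate is constant within a stage and recomputed at stage
boundaries, which is equivalent to per-epoch recomputation when the size
is constant within a stage.

## Progressive resizing and the trainer contract

A `progressive_plan` is an ordered list of stages with three monotonicity
invariants, enforced by a non-throwing validator: image sizes strictly
increasing, batch sizes non-increasing, unfreeze fractions non-decreasing.
No canonical per-size batch sizes or unfreeze counts exist for this
schedule, so the defaults — batches 64, 64, 32, 32, 16 and unfreeze
fractions 0, 0.25, 0.5, 0.75, 1 — are package choices, labelled as such
and fully configurable. The fourth stage defaults to 256 px; the
alternative 254 px convention is reachable via the `sizes` argument.

`run_progressive()` drives any trainer satisfying a three-function
contract (`init`, `train`, `predict`). Stage `k` trains from stage
`k − 1`'s output weights; every stage's input and output weights carry a
numeric fingerprint recorded in a provenance log, so the chaining is
verifiable after the fact. A trainer failure at stage `k` aborts while
preserving stages `1..k−1`. Per-stage validation and test probability
matrices are captured and can be stacked into a `prediction_set` for the
fusion module — the per-resolution stage models are exactly the "base
models" the ensembles combine.

The bundled reference trainer is a pooled-pixel linear softmax classifier:
images at any resolution are block-mean-pooled onto a fixed 8 × 8 grid
(so the weight shape is resolution-independent and chaining is
meaningful), centered by a fixed offset of 0.2, and fit by full-batch
gradient descent with step `stage_lr × 2000`, 75 steps per declared epoch
and an L2 penalty of `1e-3`. The `unfreeze_fraction` selects the trailing
fraction of feature weights that are trainable (the bias always is), so
early stages are mostly frozen, as in staged fine-tuning. It is RNG-free,
hence bit-identical across reruns. Epochs default to 8 per stage — the
problem sizes here (90 images of 3 classes in the bundled experiments) are
chosen so the whole five-stage workflow runs in seconds. A weak
monotone-benefit property (final-stage validation accuracy within 2 points
of the first stage, across 5 seeds) is asserted on the synthetic fixtures;
the strong claim that higher resolution helps real MRI classification is a
property of real data and is *not* established by these tests.

## Ensemble fusion

Fusion operates on an `n_models × n_samples × n_classes` probability
array. Every argmax tie, everywhere, breaks to the smallest class index —
a single global rule that keeps cross-method comparisons deterministic.
Soft voting is implemented as uniform-weight weighted averaging, so the
two agree exactly, not merely to rounding.

The seven strategy names admit many concrete constructions over a *fixed*
pool of stage models; the ones implemented are package definitions,
documented here:

* **Weighted averaging with optimized weights**: DCWOA searches raw
  vectors in `[0, 1]^M`, normalized onto the simplex inside the objective
  (negatives clipped, all-zero falls back to uniform). The initial
  population is seeded with all one-hot vectors plus the uniform vector;
  with the accuracy objective, elitism then guarantees the returned
  ensemble never scores below the best single model on validation. The
  default objective is cross-entropy (smooth); the accuracy objective is
  the one used for the dominance guarantee.
* **Bagging**: B seeded bootstrap resamples of the validation set; per
  resample, per-model accuracies normalize into a weight vector; final
  weights are the mean; fusion is weighted averaging.
* **Boosting**: multi-class adaptive boosting over the fixed pool — each
  round selects the model with the lowest weighted error, weights it
  `ln((1−err)/err) + ln(K−1)` (error floored at 1e-10 so a perfect model
  gets a large finite weight), up-weights its misclassified samples
  multiplicatively, renormalizes. Models may be selected repeatedly;
  selection stops when even the best weighted error reaches `(K−1)/K`.
* **Stacking**: a multinomial linear map on the concatenated per-model
  probabilities, fit on validation by full-batch gradient descent on
  L2-penalized cross-entropy (zero init, fixed step 0.5, 500 iterations —
  deterministic; zero iterations yields uniform probabilities, hence
  label 0 everywhere by the tie rule).
* **Blending**: stacking fit on a seeded 50% held-out fraction of the
  validation set.
* **Hybrid**: majority vote across the label outputs of several
  strategies.

## Metrics

Accuracy, precision, recall and F1 follow the standard TP/TN/FP/FN
definitions and are reported as percentages (two decimals in printed
output). Multiclass aggregation defaults to macro averaging; because a
single summary value for a multiclass task depends on the chosen average,
the choice is stated in the report metadata and a support-weighted
variant is a flag. Per-class precision or recall with a
zero denominator is reported as 0 and flagged, keeping macro means total.
AUC is the rank statistic (midranks on ties; equivalent to pair counting,
verified against a brute-force oracle in the tests), macro-averaged
one-vs-rest for multiclass input.

## Synthetic fixtures

* `gen_predictions()` emulates correlated classifiers of stated
  accuracies: correctness is decided by thresholding a latent uniform at
  the target accuracy, and with probability `correlation` a model reuses a
  shared per-sample latent, so errors co-occur. Correct rows are peaked on
  the true class (peak `~ U(0.65, 0.95)`), errors on a random wrong class.
  Empirical accuracies land inside binomial confidence bands by
  construction.
* `gen_images()` renders class `k` as `k + 1` elliptical Gaussian blobs
  (radii `~ U(0.08, 0.10)` of the image side, intensity `~ U(0.85,
  0.95)`) on a 0.1 background with additive Gaussian noise (sd 0.05), the
  same scene at every requested size. Blob mass is kept tight so class is
  linearly decodable from pooled pixels — the tests require a linear
  classifier to beat chance by 20 points — while positions stay random.
  These fixtures share nothing with real MRI appearance beyond "bright
  structures on a dark background"; passing tests demonstrate the
  correctness of the machinery, not clinical performance.

Both generators, and every optimizer run, are pure functions of their
configuration including the seed.

## Numerical choices and limitations

* All probability rows are validated to sum to 1 within 1e-6; simplex
  weights to 1 within 1e-9.
* Exact floating-point ties in fused probabilities are resolved to the
  smallest class index; tests that exercise the tie rule use binary-exact
  probabilities so the tie is exact in floating point.
* The whale-step oracle test compares one iteration against a naive
  transcription at 1e-12, with a frozen draw stub; determinism contracts
  are asserted with `identical()`, i.e. bit-for-bit.
* Problem sizes in tests (2-D spheres, 20-seed batteries, 90-image
  progressive runs, 2000-sample prediction fixtures) are package choices
  that keep the full suite in the low minutes while leaving the stochastic
  properties (convergence medians, recovery rates) well away from their
  thresholds.
* Parallel fitness evaluation, non-box constraints, additional chaotic
  maps (tent, cubic, singer), conditional search spaces, calibration, and
  comparisons against other metaheuristics are out of scope.
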