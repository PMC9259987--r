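---
title: "Private representation learning with dpnet: models, parameters and design choices"
author: "dpnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Private representation learning with dpnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpnet)
```

## The problem and the model

Molecular matrices — expression profiles, copy-number calls, drug-response
panels — are identifying. dpnet trains neural models on such data under
(α, ε)-Rényi differential privacy (RDP), so that the *published model*
carries a formal guarantee: its distribution changes by a bounded amount
when any single sample (one row, one patient or cell line) is added or
removed.

The workflow has two stages, each with its own privacy budget:

1. **Representation learning.** A denoising autoencoder
   (`dp_autoencoder()`) is trained on a large "second private" matrix.
   The clean input is corrupted with elementwise Gaussian noise of
   standard deviation `corruption_sd`, pushed through a dense/ReLU/dropout
   encoder to a low-dimensional code, decoded through the mirrored stack,
   and penalised by the mean squared reconstruction error against the
   *clean* input.
2. **Transfer and downstream fitting.** `encode()` maps any dataset that
   shares the feature set into the code space (inference mode: clean
   input, dropout off). A softmax classifier head (`dp_classifier()`,
   cross-entropy loss, early stopping) or a linear-output regressor
   (`dp_regressor()`, mean squared error, one independent model per drug)
   is then trained on the codes.

Both stages are trained with **DP-SGD**: each sample's gradient is clipped
to ℓ2 norm `C`, the clipped gradients are summed, Gaussian noise with
standard deviation σ·C is added to the sum, and the noisy sum is divided
by the batch size. Removing one sample changes the sum by at most `C`, so
`C` is the mechanism's sensitivity. For the Gaussian mechanism,
σ² = α·C²/(2ε_step) yields an (α, ε_step)-RDP step, and RDP composes
additively at fixed order: T steps spend T·ε_step. The accountant
(`rdp_accountant()`) plans ε_step = ε/T up front, charges every update,
and refuses to step past the plan — overspending is a hard error, because
the privacy claim is the product's core contract. Incomplete final batches
are dropped so every mechanism invocation has identical batch size and
per-step budget.

What is *not* accounted: privacy amplification by subsampling. Only plain
additive composition is used, which is conservative. No (ε, δ)-DP
conversion is performed; all budgets are reported as (α, ε)-RDP pairs. The
order α is never fixed by the theory; it is a configurable parameter with
default 2, the simplest order exceeding 1.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha` | 2 | Rényi order (> 1); all formulas are order-parametric |
| `epsilon` | 1 per stage | RDP budget; `Inf` = non-private (σ = 0). The two-stage convention grants the representation model and each downstream model 1.0 each |
| `clip_norm` | 1 | per-example ℓ2 clip `C` = mechanism sensitivity |
| `corruption_sd` | 0.1 | denoising noise; 0.1 is the best-performing value of the {0.1, 0.2, 0.3} grid for expression-like data |
| `dropout` | 0.2 | hidden drop rate (inverted dropout; identity at inference) |
| `hidden` | c(64, 32, 16) | encoder widths, mirrored decoder; the genome-scale profile c(8000, 4000, 2000) runs through the identical code path (`--genome-profile` in the CLI) |
| `patience` | 10 | early stopping: consecutive epochs without strict improvement of either validation accuracy or validation AUC |
| `learning_rate`, `batch_size`, `epochs` | per fitter | plain SGD, no momentum |

Budget unspent because of early stopping is reported as unspent, never
reallocated. Per-drug regressors are disjoint publications and therefore
own independent budgets (parallel composition).

## Numerical and design choices

**Initialisation.** `init_params()` draws He-normal weights
(variance 2/fan_in, suited to ReLU) with zero biases. For the autoencoder
this default is *provably insufficient*: a deep ReLU reconstruction
network with zero biases on standardized (zero-mean) data collapses into
the dead-ReLU attractor — the fastest initial descent direction shrinks
the output magnitude, hidden pre-activations go negative for every sample,
and the gradient through dead units is exactly zero, so the network parks
at the trivial solution (reconstruction loss equal to the input variance,
all-zero codes) and never recovers. We verified the gradients against
central finite differences to exclude an implementation error before
attributing this to the loss landscape. `dp_autoencoder()` therefore
initialises hidden biases at 0.5 (keeping units alive early) and damps the
final layer's weights by 0.1 (so the initial output is small and the first
gradients build signal correlation instead of destroying magnitude). Both
safeguards are exposed as `init_params(bias =, output_scale =)`.

**Dropout and narrow bottlenecks.** At genome scale the code has 2000
units and dropout regularises harmlessly. At desk scale a 16–32 unit
bottleneck cannot afford to lose a fifth of its units per step: dropout
0.1–0.2 measurably degrades the learned representation. The fitters keep
the 0.2 default; the package's utility experiment trains the autoencoder
with dropout 0 and documents it here as a deliberate desk-scale choice.

**The clipping regime matters more than the clip value.** When typical
per-example gradient norms are far above `C`, clipping equalises every
sample's influence (a mean of *normalised* gradients). On imbalanced
classification this vector field can be a systematically wrong direction —
we observed training loss increasing monotonically under heavy clipping
with σ = 0. When norms are far below `C`, the calibrated noise (∝ C) is
paid for sensitivity that is never used. The useful regime is *mildly
binding* clipping: inputs scaled so that typical gradient norms sit near
`C`. `standardize_codes()` implements this for classifier/regressor
inputs: codes are standardized per dimension and divided by √code_dim, so
a typical code row has unit norm and per-example gradients land near the
default `C = 1`.

**Stability.** Softmax is computed with row-max subtraction; cross-entropy
clamps probabilities at 1e-12; all budget identities are checked at 1e-9
absolute tolerance. Gradient flattening order (layer-major, each weight
matrix column-major, then its bias) is fixed and shared by the clipping
path, the noise draw and the serialized bundles, so trajectories are
bit-reproducible given a seed.

**Early stopping** evaluates once per epoch on a stratified 10% split of
the training portion (the evaluation cadence of the "ten consecutive
times" rule is not fixed by the framework; once per epoch is our choice).
Parameters are kept at the stopping point; no best-weights restore.

**The hyperparameter search** (`dp_tune()`) starts from best performance
(0, 0) and Indicator 10. A candidate improves if its (mean CV accuracy,
mean CV AUC) pair is component-wise ≥ the best with at least one strict
inequality — faithful to an element-wise "≥" rule while excluding infinite
loops on exact ties. Improvement resets the Indicator, anything else
decrements it; the loop stops at 0. Candidates are drawn by seeded
shuffling of the grid, recycling when exhausted; each setting's evaluation
seed is a fixed function of the master seed and the setting's index, so
re-evaluating a setting is deterministic and a size-1 grid terminates
after exactly 11 evaluations (1 improvement + 10 ties).

**Publication contract.** `save_bundle()` writes the model parameters (at
full double precision, for bit-identical reloads), the architecture spec
and the privacy record — never any training data, codes or other
intermediate representations. Loaders verify a format version and an MD5
checksum of the weights.

## The synthetic generator: what it emulates, what it does not

`synth_config()` / `synth_bundle()` generate the fixture every stage is
tested on: a linear-Gaussian latent-factor matrix X = ZW + noise
(defaults: 1000 samples × 200 features, rank 10, unit noise), an
imbalanced binary label driven logistically by the first factor (effect 3,
expected positive fraction 0.8, matching a 794:197-style imbalance; the
intercept is solved by numerical integration so the expected fraction is
exact), a drugs-by-samples response table with per-drug linear truth and
30% completely-at-random missingness (~700 observed samples per drug, in
the 350–850 band typical of IC50 panels), and a copy-number matrix
obtained by column-wise quantile thresholding into {−1, 0, +1}
(loss/diploid/gain). This is the minimal structure under which a
low-dimensional code is provably sufficient for both downstream tasks, so
autoencoder utility is testable against a known oracle.

It deliberately does **not** emulate gene–gene correlation structure,
batch effects, count noise, or informative missingness. Passing tests
therefore show that the mechanisms work and that the privacy accounting
holds — not that a particular real dataset would reach any particular
accuracy.

## The utility experiment and problem sizes

`run_utility_experiment(epsilon, seeds)` is the package's privacy-utility
measurement: per seed it draws the default fixture, holds out 20% of
samples, trains the autoencoder on the rest, encodes both splits, trains
the classifier on standardized codes, and reports held-out AUC. Following
the framework's own tuning philosophy (hyperparameters, including depth,
are tuned per budget), the arms use per-budget settings chosen once and
frozen: the non-private arm trains the c(64, 32, 16) profile for 40 epochs
in batches of 50 without clipping; private arms train the shallower
c(64, 32) profile for 30 epochs in batches of 200 at clip 2 (autoencoder)
and clip 1 (classifier). The shallower private profile is the noise
arithmetic made concrete: accumulated per-weight noise grows with
steps × clip / batch, and a wider, shallower code is a far more
noise-tolerant representation at desk scale.

The test suite runs this experiment at ε ∈ {∞, 10, 0.5} over five seeds
and asserts the recovery contract (non-private median AUC at least 0.85;
the ε = 10 arm within 0.1 of non-private; monotone ordering in ε with
0.05 slack). The acceptance script recomputes the same quantities from
scratch, plus a ten-drug regression panel scored by 10-fold
cross-validated Spearman rank correlation at the two-stage budget
1.0 + 1.0. Problem sizes throughout (1000 × 200 fixtures, 5 seeds,
10 drugs, 64-feature oracle fixtures) are the package's chosen desk-scale
conditions; genome-scale shapes are configuration-reachable.

## Known limitations

- The accountant is exact only for the plain Gaussian mechanism with
  uniform schedules; no subsampling amplification, no optimal-order
  search, no (ε, δ) conversion.
- The privacy cost of hyperparameter *search* is reported per candidate
  and left to the user to aggregate; the framework's stance is that tuning
  on DP representations while publishing only the final model adds no
  leakage, but cumulative accounting across candidates is not performed.
- Per-example clipping makes no fairness claim: it equalises influence,
  which on imbalanced data can change what is learned, not only how
  privately.
- DP-SGD at tight budgets barely moves a 30k-parameter network from its
  initialisation; at desk scale much of the private representation's
  utility is carried by the (data-independent) random projection plus the
  modest private refinement. This is a property of the budget arithmetic,
  not of the implementation.
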