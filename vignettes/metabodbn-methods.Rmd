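---
title: "Deep belief network classification of metabolomic peak matrices: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep belief network classification of metabolomic peak matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodbn)
```

## The problem

Aligned LC-MS peak tables are wide, sparse and small: a typical three-group
animal study yields on the order of 168 serum samples (56 each of a control
group CG, a disease-model group MG, and a treated group RG) described by
hundreds to thousands of m/z--retention-time features, many of them zero
because the peak was not detected in that sample. `metabodbn` implements a
deep belief network (DBN) classifier for such tables: unsupervised
restricted Boltzmann machine (RBM) pretraining learns a feature hierarchy
from the unlabelled intensities, a softmax head is trained on the top-layer
features, and the whole stack is then fine-tuned jointly on the labels by
full-batch gradient descent (GD) or L-BFGS, with dropout against
overfitting. The package also supplies the evaluation harness (stratified
cross-validation, SVM/KNN/BPNN baselines, per-iteration error traces,
training-size sweeps) and a synthetic peak-matrix generator so the whole
pipeline is testable without any external data.

## Model

### RBM energy and conditionals

An RBM over `n` visible and `m` hidden binary units has energy

$$E(v, h \mid \theta) = -\sum_i a_i v_i - \sum_j b_j h_j - \sum_{i,j} v_i W_{ij} h_j,$$

defining $P(v, h) \propto e^{-E(v,h)}$. Because the graph is bipartite the
conditionals factorise:
$P(h_j = 1 \mid v) = \delta(b_j + \sum_i v_i W_{ij})$ and
$P(v_i = 1 \mid h) = \delta(a_i + \sum_j W_{ij} h_j)$ with
$\delta(x) = 1/(1+e^{-x})$. `hidden_probs()`/`visible_probs()` implement
these; the test suite checks them against exhaustive enumeration of the
Boltzmann distribution on all RBMs with up to three units per layer.

Visible units are treated as unit-interval-valued: min--max-normalised
intensities in $[0,1]$ enter the positive phase directly. This matches the
sigmoid activation range and avoids a Gaussian-visible variant the
energy above does not describe.

### CD-1 training

Maximum likelihood gradients of an RBM require the intractable model
expectation; contrastive divergence replaces it with a K-step Gibbs
reconstruction (K = 1 here, one reconstruction per update):

$$\Delta W_{ij} = \varepsilon (\langle v_i h_j\rangle_{data} - \langle v_i h_j\rangle_{recon}),$$

and analogously for the biases. Conventions, since several are possible:
the positive phase uses hidden probabilities on the data; binary hidden
*samples* drive the reconstruction; the negative phase uses visible
probabilities and their hidden probabilities (the standard low-variance
choice). A test verifies that the CD-1 update direction, averaged over
10,000 seeded chains on a 3x2 RBM, has cosine similarity above 0.9 with the
exact log-likelihood gradient computed by state enumeration
(`exact_loglik_grad()`).

Updates are full-batch — one update per epoch over the whole training
matrix, no mini-batches — which suits the small sample sizes involved.

### Stacking, softmax head, fine-tuning

`dbn_pretrain()` trains RBMs greedily: each layer on the hidden
*probabilities* of the layer below (mean-field stacking, so every layer
sees deterministic inputs and pretraining is reproducible). The top-layer
activations feed a softmax head giving class probabilities; the head is
first optimised alone on frozen features (`train_softmax_head()`, L-BFGS
from zero initialisation) so fine-tuning starts from informed rather than
random head weights.

Fine-tuning (`finetune()`) treats the stack plus head as one feed-forward
network and minimises mean multiclass cross-entropy plus
$(\lambda/2)\sum w^2$ weight decay on weights (biases excluded), with the
exact backpropagated gradient (`cost_and_grad()`, verified against central
finite differences to relative error below 1e-6). Two optimisers are
provided:

* **GD** — full-batch fixed-step gradient descent (default step 0.1, no
  momentum), conventional budget 5000 iterations;
* **L-BFGS** — limited-memory quasi-Newton (two-loop recursion, history 20,
  strong-Wolfe line search with c1 = 1e-4, c2 = 0.9, gradient sup-norm
  tolerance 1e-6), conventional budget 300 iterations.

L-BFGS is implemented in the package rather than delegated to
`stats::optim` because the harness must record FMSE/FMR/TMR after *every*
iteration and resample dropout masks between iterations; `optim` exposes
neither hook. A test confirms the implementation reaches the same optimum
as `optim`'s L-BFGS-B on a fixed objective.

### Dropout

During training each hidden layer's activations are multiplied by a fresh
Bernoulli$(1-p)$ 0/1 mask; at inference activations are scaled by $1-p$ to
preserve their expectation. Masks are per-sample, per-unit matrices
(standard dropout). An earlier per-unit-vector variant shared across the
batch was abandoned: with full-batch L-BFGS the objective then changed so
much between iterations that line-search steps tuned to one mask were
catastrophic under the next, and training diverged. Within one L-BFGS
iteration the masks are held fixed, so the Wolfe conditions refer to a
single deterministic objective, and the curvature pair is formed from two
gradients under that same mask.

Defaults: dropout 0.2 during pretraining, 0.5 during fine-tuning, none on
the input layer. The rates are conventional rather than prescribed, and
configurable throughout.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `hidden` | 32, 16 | hidden-layer widths; 500-100 is the canonical choice for ~2900 variables, 100-20 for ~350 |
| `pretrain_epochs` | 100 | full-batch CD-1 sweeps per RBM (500 positive mode / 100 negative mode canonically) |
| `pretrain_rate` | 0.1 | CD learning rate $\varepsilon$ |
| `weight_init_scale` | 0.01 | SD of Gaussian weight initialisation |
| `finetune_iterations` | 300 (L-BFGS) / 5000 (GD) | optimiser cap |
| `learning_rate` | 0.1 | GD step |
| `weight_decay` | 1e-4 | $\lambda$ |
| `pretrain_dropout`, `finetune_dropout` | 0.2, 0.5 | mask rates |

## Normalisation and fold protocol

Per-variable min--max scaling to $[0,1]$ is fitted on **training folds
only** and applied to test folds, with out-of-range test values clipped and
training-constant variables mapped to 0. Missing cells are absent peaks and
are imputed to 0 at load time (counted and reported). Cross-validation
(`run_cv()`) refits the normaliser, the DBN, the head and the fine-tuned
network inside every fold; a test checksums each fold's normaliser against
a training-only refit to rule out leakage, and another verifies that
corrupting test labels changes the TMR trace but not one fitted parameter.

Folds are stratified: per-class counts differ by at most one across folds
and fold sizes by at most one overall (168 samples, k = 5 gives folds of
34, 34, 34, 33, 33, i.e. train/test 134/34 or 135/33). The canonical
134/34 split cannot hold for all five folds of 168, so the near-equal plan
is used without claiming to reproduce any particular historical split.
Report means follow table convention: per-fold accuracies rounded half-up
to two decimals, then averaged and rounded again.

## Synthetic data: what it emulates, and what it does not

`generate_peaks()` draws per-variable baseline log-intensities
$\mu_j \sim N(6, 1.5)$, applies class shifts to a planted informative set
(MG shifted by `effect_size` on the log scale, RG by
`(1 - treatment_recovery) * effect_size`, so the treated group sits between
control and model), adds $N(0, 0.5)$ log-scale noise, exponentiates, and
zeroes entries independently at the `sparsity` rate (default 0.4). A
fraction (default 0.2) of informative variables carry their effect through
a product of two latent per-sample factors with $E[uw]$ equal to the
additive shift — a non-additive effect a linear model cannot represent
exactly. Defaults mirror the canonical study shape: 3 x 56 samples, 2889
variables (positive mode) or 353 (`generate_negative_mode()`). The noise
SD of 0.5 and the nonlinear fraction are the package's own choices of a
realistic regime; the real study's sparsity and effect structure are
unreported, so none of these values can claim fidelity to it.

Two emulation choices matter for interpreting test results:

* **Zeros are class-independent.** Each entry is masked with the same
  probability regardless of group, so absence carries no signal and acts
  purely as noise. In real peak tables absence is often intensity- and
  group-dependent and therefore informative. This makes the synthetic task
  *harder* than comparable real data: an oracle that knows the planted
  distributions and skips zeros separates the default separable
  configuration perfectly, while any method that must treat 0 as an
  ordinary intensity — as this pipeline, and any pipeline with
  zero-imputed min--max inputs, does — loses substantial accuracy to the
  40% masking noise. Cross-validated accuracy on the 168 x 300
  `effect_size = 2` configuration rises from ~84% at sparsity 0.4 to ~90%
  at 0.2 and ~94% at 0, with the identical model. High accuracy on real
  tables therefore does not follow from, and is not contradicted by, the
  accuracy ceiling on this generator.
* **Min--max on raw intensities interacts with large effects.** The
  per-variable maximum is dominated by the upshifted class, so increasing
  `effect_size` beyond ~2 *compresses* the remaining classes' contrast
  rather than improving it.

Passing tests on this generator show the machinery — pretraining,
gradients, optimisation, the harness — is correct and that planted signal
of realistic size is recovered well above baselines (the same protocol
gives glmnet ~70%, SVM ~71%, KNN ~52% on the separable configuration);
they do not certify any particular accuracy on real UPLC-MS data.

## Numerical choices and degenerate inputs

* `sigmoid()` uses `plogis`, stable to |x| around 700; cross-entropy clamps
  probabilities at 1e-300 before `log`.
* Softmax subtracts the row maximum before exponentiation.
* Parameter flattening order (fixed, for serialisation and optimiser
  interchange): per layer bottom-up, `vec(W)` column-major then hidden
  biases; finally softmax weights then softmax biases. RBM visible biases
  belong to the generative model only and are not fine-tuned.
* Prediction ties break toward the earliest class in `class_order`
  (sorted label strings unless overridden).
* Training-constant variables normalise to 0; an L-BFGS direction that is
  not a descent direction resets the history to steepest descent; a failed
  line search falls back to a small safe gradient step.
* Every stochastic step is a pure function of the supplied seed: child
  seeds for pretraining layers, head training, fine-tuning masks and CV
  folds are derived deterministically from the top-level seed, and two
  runs of `cmd_crossval()` with the same config produce byte-identical
  outputs.

## Problem sizes used in the checks

The shipped checks run at sizes chosen to exercise the full pipeline
quickly: oracle equivalences on RBMs with at most three units per layer;
the optimizer contrast on the full 168 x 2889 default generator with a
d-32-16-3 network, 100 CD epochs, a 300-iteration L-BFGS cap and a
1500-iteration GD run; cross-validated recovery at 168 x 300 with a
300-100-20-3 network (the canonical shape for ~300 variables), 100 CD
epochs and 300 fine-tuning iterations. The canonical full budgets (500 CD
epochs, 5000 GD iterations) remain the defaults of the command-line
presets.

## Known limitations

* Binary/unit-interval visible units only; no Gaussian-visible RBM, so
  heavy-tailed inputs rely on the min--max squash.
* CD-1 only (no persistent CD or tempering); generative quality of the DBN
  is not a goal, the stack exists to initialise the classifier.
* Full-batch optimisation throughout; no stochastic optimisers.
* The accuracy ceiling induced by class-independent zero-masking in the
  generator (discussed above) is a property of the synthetic conditions,
  not a bug to be tuned away; analyses of real tables should revisit the
  zero-handling (e.g. detection-aware imputation) before the sigmoid
  pipeline.
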