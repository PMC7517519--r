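---
title: "Separated-channel CNNs with additive attention for multi-site fMRI classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separated-channel CNNs with additive attention for multi-site fMRI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state fMRI classification studies that pool data from several
acquisition sites face two obstacles at once: the raw measurement is a
*variable-length* multivariate time series (sites scan for different
durations, from 50 to 257 volumes in the five-site layout this package
emulates), and the sites differ systematically in scanner gain, baseline,
class balance and sample size. Hand-crafted summaries such as functional
connectivity discard the temporal dynamics; a classifier trained on one
site rarely transfers to another.

`sccnn` implements a two-stage network that addresses both obstacles
directly, together with the evaluation protocol that makes the multi-site
claim testable and a synthetic cohort generator that makes every stage
verifiable without any imaging download.

## The model

**Stage 1 — separated-channel encoder.** Each brain region contributes
one channel: its region-mean BOLD series. A single temporal
convolutional network — *one* parameter set, shared by all `R` regions —
is applied to every channel independently. After the final convolution,
each filter's feature map is averaged over its valid time positions
(temporal global average pooling). Averaging is what absorbs the length
heterogeneity: a series of any admissible length `T` maps to the same
`R x D` feature matrix `H`, where `D` is the last layer's filter count.
Sharing is what keeps the parameter count independent of `R` and
prevents the per-region branches from overfitting their own channel.

**Stage 2 — pairwise additive attention.** With `h_n` denoting row `n`
of `H`, every ordered pair of regions is scored

    g(n, n') = tanh(W_g h_n + W_g' h_n' + b_g)
    alpha(n, n') = sigmoid(W_a g(n, n') + b_a)

and the fused representation of region `n` is the gated sum
`l_n = sum_{n'} alpha(n, n') h_{n'}`. Two conventions deserve emphasis
because both differ from the transformer-style default:

* the gate is a **sigmoid, not a softmax** — each pair is thresholded
  independently and the weights over `n'` do not sum to one (a softmax
  variant would change the model class; it is deliberately not applied);
* the self-pair `n' = n` **is included** in the sum, since the fusion
  runs over all `n'`.

The flattened `R x D` fused matrix feeds a softmax layer that outputs
the two class probabilities. For ablation the package also provides the
plain head (`"none"`: flattened `H` straight into the softmax — the
plain SC-CNN), a rectified fully connected head (`"dense"`), and a
bidirectional LSTM over the region sequence (`"lstm"`).

**Optimization.** Adam (default moment parameters) with initial step
size 0.01, cross-entropy loss, L2 penalty on multiplicative weights,
Xavier initialization, and class-balanced minibatches: every batch of 32
holds exactly 16 cases and 16 controls drawn with replacement within
class. Balanced batching is the guard against the prior collapse that
imbalanced cohorts otherwise induce.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `filters`, `kernel_size` | 32/32/64, 7 | encoder capacity; the 3-layer default keeps the minimum admissible length (46) below the shortest site run (50) |
| `pooling` | max-2 between layers | temporal downsampling; between layers only, so the final average sees every valid position |
| `d_a` | `D` | attention hidden width (the architecture text leaves it open) |
| `learning_rate` | 0.01 | Adam initial step size |
| `l2_coefficient` | 1e-4 | weight decay (value not dictated by the architecture; biases exempt) |
| `batch_size` / `per_class_per_batch` | 32 / 16 | balanced batching contract |
| `max_steps` | 200 | no stopping rule is dictated; see below |
| `standardize` | TRUE | per-region, per-subject z-scoring |

Two open choices are resolved as follows and exposed as switches:

* **Input scaling.** Nothing in the architecture fixes a scaling of the
  input series, but sites differ in gain and baseline, so the pipeline
  z-scores each region of each subject by default. The transform is
  per-subject, so it cannot leak information across cross-validation
  folds.
* **Stopping.** Training runs a fixed number of balanced-batch steps.
  For the desk-scale benchmark below, 250 steps is where the training
  cross-entropy plateaus (below ~0.05); shorter budgets leave the model
  visibly undertrained and, occasionally, miscalibrated on a held-out
  site even when its ranking (AUC) is already perfect.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the *statistical structure* the method
must survive: five sites with the published per-site case/control counts
(35/69, 36/37, 151/111, 43/70, 102/143), per-site run-length pools
(152/119, 257, 176/172, 78/50/73, 236/231), site gain and baseline
offsets, and a 116-region matrix per subject. The background is a
stationary AR(1) series per region; the class signal lives in a small
set of informative regions under one of three mechanisms (added
oscillation, class-dependent oscillation frequency, or a shared
low-frequency latent loaded on cases).

Because the pipeline z-scores each region, a class signal is only
recoverable through the *spectral shape* it induces — a pure gain
difference would vanish. All three mechanisms therefore inject
low-frequency structure; this also mirrors where real BOLD class effects
are usually sought. The coupling latent is a slow sinusoid with a
per-subject random phase shared across the informative regions.

The generator deliberately does **not** simulate hemodynamics, head
motion, physiological noise or spatial maps. A passing benchmark on this
cohort shows that the architecture's mechanics work — variable lengths,
imbalance, cross-site generalization, signal recovery — not that any
particular accuracy transfers to real imaging data.

One base seed drives the whole cohort through per-subject derived
seeds, so adding a site or subject never changes anyone else's series,
and a cohort is byte-reproducible from its seed.

## Numerical choices

* Convolutions are "valid" (unpadded) and the temporal average divides
  by the true number of valid positions. Padding would dilute short
  series, and batching must not change any subject's encoding: a mixed
  length batch is grouped by length internally and reproduces
  single-subject evaluation to floating-point accuracy.
* Max-pooling ties resolve to the earlier time position,
  deterministically.
* A constant region z-scores to all zeros rather than dividing by zero.
* The log-loss clamps probabilities at 1e-12; training aborts with a
  diagnostic if the loss is ever non-finite.
* All hot loops (im2col, rectifier, temporal average, pairwise tanh
  sheets) are small compiled kernels operating on a flat time-major
  layout; the linear algebra is BLAS. The compiled path is numerically
  identical to the reference formulas, which the test suite checks
  against scalar triple-loop oracles and finite-difference gradients.

## The evaluation protocol

`loso_folds()` holds out each site in turn: the fold's test set is
exactly that site. Per fold, a fresh model is Xavier-initialized from a
fold-derived seed and trained on the remaining sites only; nothing from
the test site (subjects, statistics, batch pools) is touched before
prediction. Accuracy uses the 0.5 threshold; AUC is the rank-sum
(Mann-Whitney) statistic with ties counted one half, scoring cases by
their softmax probability.

The benchmark report gives per-site accuracy and AUC per head plus two
overall columns: the unweighted mean over sites and the subject-weighted
mean. Both are reported because with site sizes this unequal the two
summaries genuinely differ, and published tables are not always explicit
about which one they print.

## The desk-scale benchmark

The acceptance experiment scales the five-site counts by 0.37 (296
subjects), keeps all 116 regions and the real length pools, plants a
coupling signal of twice the noise standard deviation in 12 spread-out
regions, and uses a reduced encoder (one layer, 8 filters, kernel 7,
attention width 4) so that the whole leave-one-site-out comparison runs
on one CPU in minutes. Under these conditions the attention model
recovers the signal on every held-out site and a zero-effect cohort
stays at chance (the binomial test of pooled held-out accuracy against
0.5 does not reject).

## Known limitations

* **Gate saliency is not sign-guaranteed.** Because the gate is an
  unnormalized sigmoid and the classifier reads the *entire* flattened
  fused matrix, the network can exploit a planted signal equally well by
  up- or down-gating the informative regions. On the converged synthetic
  benchmark the informative regions do end up receiving a small but
  highly consistent surplus of attention weight, but at shorter training
  budgets the sign of the difference can flip while classification is
  already perfect. The mean received attention weight is therefore a
  class-sensitive but not direction-reliable saliency measure; treat
  attention-weight maps as descriptive, not as a biomarker ranking.
* **At saturating effect sizes the attention head has no headroom.**
  When the planted signal is strong enough that the plain flattened
  head classifies every site perfectly, the attention model can only
  match or lose; in the benchmark it matches on four sites and drops a
  few subjects on the shortest-run site (50–78 samples, against
  training runs of 119+), where the temporally averaged features are
  noisiest and the multiplicative gate compounds that noise (its
  ranking there remains near-perfect, AUC ≈ 0.995). Separating the
  heads requires effect sizes below the plain head's ceiling.
* Per-region encoding cannot, by construction, detect a class signal
  that lives purely in cross-region correlation with identical
  per-region marginals; the attention stage mixes features, not raw
  series.
* Cross-site threshold calibration is the weak point of hard 0.5
  thresholding: a fold can reach AUC 1.0 yet mediocre accuracy if the
  held-out site's score distribution is shifted. Training to the loss
  plateau largely removes this on the synthetic cohort, but on real data
  a calibration step would be warranted.
* The atlas and volume must already share a voxel grid; no registration,
  resampling, motion correction or filtering is performed (those belong
  to the upstream preprocessing pipeline).
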