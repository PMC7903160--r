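---
title: "Adversarial unlearning of scanner effects: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial unlearning of scanner effects: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(unlearnr)
```

## The problem

Pooling structural MRI across scanners and acquisition protocols inflates
non-biological variance: contrast, bias-field and noise signatures differ
between sites, and a network trained on pooled data will happily exploit
them. A feature representation that encodes the scanner can drive
predictions by site rather than by biology, and it generalises poorly to
new scanners. Harmonisation, in the sense used here, means learning a
representation that is *discriminative for the task* (age regression or
tissue segmentation) while *uninformative of the acquisition site*.

`unlearnr` implements an iterative adversarial scheme for this. A network
is split into a feature extractor (parameters $\Theta_{repr}$), a label
predictor ($\Theta_p$) and a domain classifier ($\Theta_d$), the latter
attached to the fixed-length representation $Q_{repr}$ at the end of the
extractor. Training alternates three stages on each batch:

1. **Main task** — minimise the task loss $L_p$, evaluated per scanner and
   summed over scanners so that no site dominates by size,
   updating $\Theta_{repr}$ and $\Theta_p$:
   $L_p = \sum_{n=1}^{N} \frac{1}{S_n} \sum_{j=1}^{S_n} \ell(y_{j,n}, \hat y_{j,n}).$
2. **Domain classification** — minimise the categorical cross-entropy
   $L_d = -\frac{1}{S_u}\sum_s \sum_k \mathbb{1}[d_s = k] \log p_{s,k}$
   updating $\Theta_d$ only; this fits the best classifier for the current
   representation and thereby *measures* how much scanner information
   remains.
3. **Confusion** — minimise
   $L_{conf} = -\frac{1}{S_u}\sum_s \frac{1}{N} \sum_k \log p_{s,k}$
   updating $\Theta_{repr}$ only. Its minimum, $\log N$, is attained
   exactly when every softmax output is uniform, i.e. when the fitted
   classifier has nothing left to work with.

Stages 2 and 3 act in opposition and cannot be merged; the classifier is
always updated first so the confusion gradients point at information that
is actually present. The combined objective,
$L = L_p + \alpha L_d + \beta L_{conf}$, extends per removed confound $j$
by a classification/confusion pair weighted $\gamma_j, \phi_j$. Success is
measured post hoc by a *probe*: a freshly initialised domain classifier
trained to convergence on the frozen features; accuracy at the chance level
$100/N\%$ means no recoverable scanner information.

Subset flags route samples to the losses: `in_p` (task loss; requires a
label), `in_u` (scanner unlearning; needs no task label — the basis of
semi-supervised training), and per-confound `in_c`. The
`unlearning_policy()` modes implement the study designs: unlearning on
everything, on the inter-site age-overlap window only (biased-domain
designs), or on a confound-balanced subsample.

## What the synthetic generator emulates

`generate_phantom()` renders a 2D head-like phantom with three tissue
compartments: an outer CSF ring, a GM annulus and a WM disc with a central
CSF-filled cavity. The biology-like signal is geometric: the cavity radius
grows and the GM annulus thins with age, monotonically. Sex enters only as
a small lateral offset of the central cavity — deliberately orthogonal to
the radial age signal, so that removing sex information does not have to
cost age accuracy. Scanner effects are applied per site as gamma contrast,
a smooth multiplicative bias field (five low-order polynomial basis
functions with site-specific coefficients), a global intensity scale, and
additive Gaussian noise, in that order, so the effects interact as they
would in acquisition. Because every image is z-normalised downstream, the
durable scanner signatures are contrast, bias pattern and noise level;
`default_site_effects()` keeps them *moderate*: harmonisation addresses
subtle protocol differences, not different modalities.

`generate_dataset()` adds the population structure: per-site age ranges
(uniform), configurable range overlap (`make_overlap_ranges()`),
confound–site or confound–age correlation (e.g. 80% male at one site),
per-site label availability, and a per-subject *biological age gap*
(`biological_sd`, default 6 years) between chronological age and the age
that drives the geometry. The gap matters twice: it reproduces the
irreducible error floor of real brain-age models (a few years, not a
fraction of a year), and it creates the incentive for a pooled model to
lean on the site-conditional age prior — the mechanism behind the
biased-domain failure mode. All randomness derives from the design seed by
a fixed integer-hash splitting scheme; rendering is bit-reproducible.

What the phantoms do **not** model: 3D anatomy, MR physics (no k-space, no
relaxometry), registration error, motion, pathology, or realistic
anatomical variability beyond the two geometric factors. Passing tests on
phantoms therefore show that the training machinery removes recoverable
site information under controlled conditions; they do not certify
performance on real cohorts.

## Making the adversarial game converge at desk scale

The three-stage scheme as literally written — one optimiser step per stage
per minibatch with a shared learning rate — removed essentially no
probe-recoverable information in our experiments at this scale. The
package's unlearning phase for the encoder models therefore adds five
design elements, each addressing a specific failure mode we observed:

* **Adversarial balance is a learning-rate ratio.** With Adam, loss
  weights barely matter (updates are magnitude-normalised), so the
  classifier must out-pace the extractor by rate: heads use `lr_head`
  (default 1e-2), the confusion updates `lr_conf` (default 3e-3), task
  maintenance during unlearning `lr_task_unlearn` (default 3e-4). If the
  extractor wins the inner game it merely *hides* information from the
  current classifier — a converged probe still reads it.
* **Attach-point scope.** After pretraining, the convolutional bank is
  frozen and stages 1 and 3 update the fully connected projection that
  produces $Q_{repr}$ (`unlearn_scope = "attach"`). The game is then
  played over a stationary feature distribution, the classifier can be
  fitted full-batch to near-optimum each epoch (`head_steps_full`), and
  the whole phase runs on cached features. The U-Net uses the full scope.
* **Fresh adversaries.** The domain classifier is re-initialised every
  `head_reinit` epochs. The post-hoc probe is freshly initialised, so the
  training-time adversary must be comparably strong; warm-started heads
  get stuck in stale basins and under-report residual information.
* **Unit-variance features.** A parameter-free batch normalisation at
  $Q_{repr}$ (batch statistics in training, running statistics at
  inference) prevents the extractor from hiding site information in
  low-variance directions that a standardising probe would amplify.
  Adversarial stages do *not* update the running statistics: their batches
  are policy subsets (e.g. overlap ages only) and would skew the
  population statistics used at inference.
* **Averaging and checkpointing.** The equilibrium oscillates — the
  direction of the residual information rotates between epochs — so the
  projection, predictor and statistics are Polyak-averaged
  (`ema_decay`), and checkpoints are scored every `check_every` epochs by
  a validation probe (computed on an age-matched subset, so an age–site
  association cannot stand in for the site label) plus a penalty for task
  degradation. The selected checkpoint is the most harmonised one whose
  validation task loss stays within `task_tolerance` of the pretrain-exit
  loss; the pretrained state itself is checkpoint 0, so if unlearning
  cannot proceed without destroying the task — which genuinely happens
  when the main-task label is strongly coupled to the site and unlearning
  is run naively on everything — training falls back to it rather than
  return a broken model. Finally the label predictor alone is refit on the
  frozen representation, which recovers averaging lag without touching
  $Q_{repr}$.

Remaining numerical choices: natural logarithms throughout; probabilities
floored at 1e-8 inside logs; soft age labels evaluate the
$N(\mu, \sigma^2)$ density ($\sigma$ = 10 years) at 1-year bin centers over
0–100 years and renormalise, with KL(true ‖ predicted) as the task loss and
the expectation over bins as the point estimate; soft Dice uses
$\epsilon$ = 1e-5 with the background class excluded from the average;
Dice ties and label-map threshold ties resolve to the lowest class index;
average pooling (smooth gradients, trivial adjoint) rather than max
pooling in the miniature encoders; He-scaled Gaussian initialisation.

## Volume preprocessing

Real volumes are cubic-spline resampled (separable natural splines, each
axis a precomputed linear operator) to a 1 mm isotropic grid over a centred
128 mm field of view, then every fourth axial slice is retained (0-based
indices 0, 4, …, 124 — 32 slices), then the result is normalised to zero
mean and unit variance over the full grid (no brain mask). The field-of-view
rule resolves an ambiguity: an object larger than 128 mm cannot keep its
physical size on a 128-voxel 1 mm grid, so the package crops/pads around
the volume centre and documents it. Label maps follow the same grid with
trilinear interpolation per one-hot channel and a 0.5 threshold.

## Problem sizes and experiment designs

The validation experiments are sized for a single CPU: the central
harmonisation study uses 3 sites × 300 phantoms of 32×32 pixels (the
probe-to-chance contrast is insensitive to this beyond a few hundred
samples per site); the biased-domain study uses two sites of 280 and 70
subjects — the size dominance mirrors the situation where one cohort is
several times larger — with a 10-year overlap inside a 15–95 year span and
a wide (field-strength-like) scanner contrast; the confound study uses two
sites × 200 with an 80/20 sex–site correlation; the semi-supervised
segmentation study uses two sites × 120 with no labels at site B.
Evaluation cohorts are freshly generated from the same designs (full age
span, balanced confounds). In the biased-domain study, "normal training"
denotes the framework's normal mode (per-scanner-weighted task loss, no
adversarial stages); when naive whole-distribution unlearning trips the
task guard on every checkpoint — the expected failure under strong
label–site coupling — it returns the pretrained model, so its margin over
normal training can be exactly zero while overlap-restricted unlearning
improves on both.

## Known limitations

* The attach-scope phase assumes the pretrained convolutional bank spans
  task-sufficient, site-invariant directions for the projection to select;
  with extreme scanner contrasts this can fail, and the fallback returns
  the pretrained model (reported honestly by the probe).
* Probe accuracies on a few hundred held-out samples carry binomial noise
  of several percentage points; orderings between training variants close
  to a tie should be read accordingly.
* The 2D miniature architectures are not the full-scale 3D networks; the
  package exposes `width_scale`, `feature_dim` and the architecture
  builders so larger variants can be configured, but no pretrained weights
  are provided.
* Checkpoint selection uses a validation probe; like any model selection
  on a finite validation set it is slightly optimistic, which is why all
  reported probes are recomputed from scratch on evaluation data.
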