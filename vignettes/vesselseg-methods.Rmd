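---
title: "Unsupervised cerebrovascular segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised cerebrovascular segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Time-of-flight MR angiography (TOF-MRA) shows flowing blood as bright
voxels without a contrast agent, which makes it the standard sequence for
imaging the cerebral vasculature. Manual vessel annotation of a 3D TOF-MRA
volume is expensive, so supervised deep segmentation models are hard to
train at scale. `vesselseg` implements an unsupervised alternative: a
classical statistical segmenter — a Gaussian hidden Markov random field
(HMRF) optimized by EM — produces three-class *pseudo-labels* (background,
brain tissue, vessel), and those pseudo-labels train encoder-decoder
networks which then segment unseen volumes. The networks can outperform
their teacher because max-pooling lets them generalize vessel appearance
across spatial scales, while the HMRF sees only voxel intensity and local
label smoothness.

Inputs are assumed preprocessed: skull-stripped and bias-corrected, with
background voxels exactly zero. Preprocessing itself (BET-style brain
extraction, bias-field correction) is out of scope; the phantom generator
emits volumes that already satisfy the contract.

## The Gaussian HMRF model

Let $y_i$ be the intensity at voxel $i$ and $x_i \in \{0,\dots,L-1\}$ its
hidden class. Each class emits intensities from a Gaussian,
$p(y_i \mid x_i = l) = g(y_i; \mu_l, \sigma_l)$, and the label field
carries a Potts prior over a 3D neighborhood system:
$$U(\mathbf{x}) = \beta \sum_{\{i,j\}\ \mathrm{neighbors}} \mathbf{1}[x_i \neq x_j],$$
each unordered pair counted once. The MAP labeling minimizes the posterior
energy
$$U(\mathbf{x} \mid \mathbf{y}) = \sum_i \left[ \frac{(y_i - \mu_{x_i})^2}{2\sigma_{x_i}^2} + \log \sigma_{x_i} \right] + U(\mathbf{x}),$$
the sum of the likelihood energy and the prior energy (partition constants
cancel in the minimization and are never evaluated; the additive constant
is fixed at zero, so the reported posterior energy is exactly
likelihood + prior).

Design choices where the model family leaves freedom:

* **Clique potential.** The pairwise Potts form above, with a single
  coupling `beta` (default 1.0). It is the standard choice for
  intensity-based HMRF segmentation and the simplest potential consistent
  with a clique expansion.
* **MAP optimizer.** Iterated conditional modes (ICM): raster-order
  sweeps reassigning each voxel to the class minimizing its local
  conditional energy, stopping when a sweep changes nothing or after
  `max_icm_iters` (default 10) sweeps. ICM is deterministic and
  monotone — every accepted move lowers the posterior energy, which the
  test suite asserts on every run. Graph cuts or annealing could find
  deeper minima but sacrifice determinism and speed; they are non-goals.
* **Ties** in the per-voxel argmin break toward the lowest class index,
  for determinism.
* **Neighborhood.** 6-neighborhood by default (the smallest standard 3D
  system), 26 available via `hmrf_config(neighborhood = 26)`. The HMRF
  runs volumetrically, not per-slice.
* **Initialization.** Seeded k-means on the (masked) intensities, with a
  quantile split as the degenerate-input fallback; cluster order is
  normalized to ascending mean. K-means is deterministic given the seed
  and robust to the strong bimodality of vessel/tissue intensities.
* **EM loop.** Each iteration runs E-step (responsibilities), M-step
  (parameter re-estimation), then ICM relabeling, and stops when the
  relative posterior-energy change drops below `tol` (default `1e-4`) or
  after `max_em_iters` (default 20). Running ICM last keeps the returned
  labels consistent with the returned parameters (with `beta = 0` the
  output is exactly the per-voxel Gaussian ML classification).
* **E-step.** Responsibilities combine the emission density with the
  local prior given the current neighbor labels,
  $P(l \mid y_i) \propto g(y_i;\theta_l)\exp(-\beta\,d_{il})$ with
  $d_{il}$ the number of in-mask neighbors not labeled $l$; computed in
  log space, with a uniform fallback (and a warning) if every class
  underflows at a voxel.
* **M-step.** Responsibility-weighted mean and standard deviation. The
  variance update uses the *updated* mean $\mu_l^{(t+1)}$ — using the
  stale mean breaks EM monotonicity. Standard deviations are clamped
  below by `sigma_floor` (default $10^{-3}\times$ the intensity range)
  because a class that captures a near-constant intensity region would
  otherwise collapse to $\sigma \to 0$ and produce infinite densities. A
  class with negligible total responsibility keeps its previous
  parameters, with a warning.
* **Masking.** When a mask is supplied, all energies, neighbor counts and
  parameter updates are restricted to it; pairs crossing the mask
  boundary are excluded. Background is fixed by contract, not modeled.

### Pseudo-labels

`make_pseudo_labels()` fixes intensity-zero voxels as background (class
0) — never re-estimated — and fits a *two*-class Gaussian HMRF inside the
nonzero brain mask. The lower-mean class becomes brain tissue (class 1),
the higher-mean class vessel (class 2), exploiting the bright-blood TOF
contrast. This yields exactly three output classes while modeling only
the two that have meaningful intensity distributions.

## The synthetic phantom

No public annotated TOF-MRA cohort accompanies this problem setting, so
the package ships a generator whose cases have exact ground truth. A
phantom is a brain-shaped ellipsoid (semi-axis fraction
`brain_radius_frac = 0.42` of each grid dimension) of Gaussian tissue
intensity containing `n_trees = 3` vessel trees grown by recursive binary
branching (depth 3) with smoothly-curving random-walk centerlines; child
radii shrink by `radius_decay = 0.75` from a root radius of 1.8 voxels.
Intensity statistics default to tissue $\mathcal{N}(90, 10^2)$ and vessel
$\mathcal{N}(220, 10^2)$ — a 13$\sigma$ class separation representative
of large-artery contrast in TOF-MRA after bias correction — and the
defaults deliberately satisfy the Gaussian-per-class assumption of the
HMRF *exactly* (`noise_sigma = 0`, `bias_amplitude = 0`), so that tests
against phantom ground truth isolate algorithm correctness from data
realism. Both degradations are available as knobs: additive Gaussian
noise, and a multiplicative second-order-polynomial bias field of
strength `bias_amplitude`, for robustness experiments. At the default
64³ grid the vessels occupy roughly 2–3% of brain voxels, matching the
extreme class imbalance of real angiograms (and staying under the 5%
sparsity contract of `phantom_case`).

What the phantom does *not* emulate: flow-related signal loss, partial
volume at vessel walls (rasterization is hard in/out, keeping ground
truth unambiguous), anatomically realistic Circle-of-Willis topology, and
scanner noise statistics (Rician rather than Gaussian). Passing phantom
tests therefore demonstrates correctness of the estimation machinery
under its stated assumptions, not clinical performance.

A "stroke-like" variant prunes one random subtree from a grown tree,
emulating the reduced vessel count of occluded circulation; the matched
healthy/stroke pair shares its geometry seed.

## The encoder-decoder networks

Two architectures consume the pseudo-labels. Since no deep-learning
backend is part of the package's dependency set, the layers are
implemented in-package: im2col + GEMM convolutions (2D and 3D, stride-1
'same'), batch normalization, ReLU, 2× max-pooling with stored argmax
indices, SegNet-style max-unpooling (nearest-neighbor upsampling as an
alternative mode), kernel-2 stride-2 transposed convolution, a soft-max
head with voxel-wise categorical cross-entropy, and mini-batch SGD with
momentum. All layer gradients are verified against central finite
differences in the test suite.

* **SegNet2D** (`build_segnet2d`): 8 convolutional layers (3×3, equal
  filter count per layer; reference 80 filters at 256×256 input), each
  with batch-norm + ReLU; two pooling stages in the encoder, mirrored by
  two max-unpooling stages in the decoder at symmetric positions
  (conv×2-pool-conv×2-pool / unpool-conv×2-unpool-conv×2). The soft-max
  head needs one channel per class, so a 1×1 class-score convolution
  follows the eighth feature convolution. Three *independent* sub-nets
  are trained, one per anatomical axis (axial, coronal, sagittal), and
  their per-voxel probability maps are averaged arithmetically — the mean
  of points on the simplex stays on the simplex.
* **U-Net3D** (`build_unet3d`): patch-based (reference 64³ patches), an
  encoder of 6 convolutions with two pooling stages doubling channels,
  and a decoder of 2 up-convolutions and 2 convolutions; each up-sampled
  feature is concatenated with the resolution-matched encoder feature
  before the following batch normalization. Inference stitches
  sliding-window patches (default stride = half the patch side, grid
  edge-shifted so every voxel is covered) by averaging overlapping
  probabilities, which preserves the simplex.

Training follows the reference recipe — SGD with momentum 0.9, learning
rate 0.001, 50 epochs, batch size 50 (2D) / 8 (3D) — exposed through
`train_config()`. The loss is voxel-wise categorical cross-entropy;
because vessels are ~1% of voxels, optional per-class weights are
available (`class_weights = "inverse"` uses inverse class frequencies of
the training labels), off by default. Slices are resized to the network
input size with bilinear interpolation; labels with nearest-neighbor
(which preserves constants and round-trips exactly); predicted per-class
probability slices are resized back to the native slice geometry and
renormalized per pixel before stacking, since bilinear resampling does
not exactly preserve unit sums. Intensities are normalized to [0, 1] per
volume at both training and inference time.

## Evaluation

Scoring follows the MIP protocol: the binary vessel mask is projected
along the axial, coronal and sagittal axes by per-pixel maximum (logical
OR for binary masks), and each projected pair (prediction vs reference)
is scored with accuracy, sensitivity, specificity, precision and the Dice
similarity coefficient $\mathrm{DSC} = 2\mathrm{TP} / (2\mathrm{TP} +
\mathrm{FP} + \mathrm{FN})$. With phantoms the reference MIPs are exact
projections of the ground-truth vessel mask. Ratios with zero
denominator are reported as `NaN` with a warning, never silently as 0.
Post-processing of predicted masks defaults to none; an optional
connected-component filter (26-connectivity, keep components of at least
`min_size` voxels) is available, since small-island removal is the one
plausible cleanup for sparse vessel masks. Across cases, two aggregation
orders are reported: the unweighted mean of per-case cross-axis means,
and metrics of the pooled confusion counts.

## Desk-scale study sizes

The shipped tests and the acceptance script run the full workflow at
reduced size so that a complete run stays within a desktop CPU budget:
48³ phantoms, a cohort of 8 cases split 6 train / 2 test, SegNet input
48×48 with 8 filters, 16 epochs at learning rate 0.02 with batch size 8
and inverse-frequency class weights. The larger learning rate and the
class weighting compensate for the far smaller number of gradient steps
than the reference recipe (hundreds rather than tens of thousands);
without the weighting, the vessel class — under 1% of pixels — is not
learned within the step budget. The headline check is *non-inferiority*:
on held-out phantoms the ensemble's vessel DSC must be within 0.05 of
its HMRF teacher's DSC. (At clinical scale the student clearly overtakes
the teacher; at desk scale, with a near-perfect teacher on high-contrast
phantoms, matching it is the meaningful bar.) The 3D U-Net trains at 16³
patches in the tests' overfit smoke checks; its full-size configuration
is available but not exercised in the default suite for time reasons.

## Numerical notes and limitations

* Posterior energies are accumulated in double precision; the ICM
  monotonicity assertion allows a $10^{-6}$ relative slack for float
  summation order.
* `segment_hmrf` reports voxels outside the mask as class 0 by
  convention; they take no part in any energy or update.
* EM convergence is declared on relative posterior-energy change, which
  can trigger early on plateaus; `tol = Inf` forces exactly one
  iteration (useful for testing), `tol = 0` is disallowed.
* The CNN engine is CPU-bound and sized for small studies; it is not a
  general deep-learning framework (no GPU, no autograd beyond the layers
  listed, batch-norm statistics are per-batch with running-average
  inference).
* The k-means initialization subsamples very large masked volumes
  (seeded) at 20,000 voxels for speed; parameter estimates are then
  refined by EM on all voxels.
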