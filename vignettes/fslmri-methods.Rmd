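---
title: "Methods: joint learning of MRI sampling, reconstruction and segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint learning of MRI sampling, reconstruction and segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Compressed-sensing MRI acquires only a fraction $\alpha$ of k-space, the 2D
Fourier domain in which the scanner measures.  With image $x$, full
measurements $y = F x$ and a binary trajectory $M$ with budget
$n = \alpha \cdot H W$, the observed data are $M \odot y$, and the
zero-filled image $F^{-1}(M \odot y)$ is the artifact-laden baseline.
Classically the trajectory is hand-crafted (variable-density random points,
or whole Cartesian phase-encoding lines), the reconstructor is trained
separately, and any downstream analysis (here: tissue segmentation) is an
afterthought.  `fslmri` implements the alternative this package is built
around: the trajectory, the reconstruction and the segmentation are one
differentiable computation, trained jointly, with the acquisition unrolled
over $P$ progressive iterations so that what has been seen so far decides
what is measured next.

## Modules

**Measurement sensing (MSM).**  A small 4-level convolutional
encoder–decoder maps three channels — the current zero-filled magnitude,
the previous semantically refined reconstruction, and the current mask — to
a per-location probability map over k-space.  Already-acquired locations
are forced to probability zero (no re-sampling).  The map is rescaled in
closed form so its mean equals the per-iteration rate exactly:
multiplicative $p \cdot r/\bar p$ when $\bar p \ge r$, complementary
$1 - (1-p)(1-r)/(1-\bar p)$ otherwise; both branches keep values in
$[0,1]$, have exact means, and differentiate cleanly.  During training a
seeded uniform matrix $u$ is subtracted (`scores = p - u`), making
selection a Monte-Carlo search whose positive-score fraction has
expectation $r$; at inference the scores are the probabilities themselves,
so inference is deterministic.  The top-$n$ scores (2D), or the top lines
by frequency-encoding sums (1D), become the next mask increment.  The
binarization is hard in the forward pass and passes gradients through
unchanged (straight-through), which is what keeps the sampler trainable.

**Reconstruction (SFRM).**  The default backbone keeps two interacting
branches, one convolving k-space values and one the image, exchanging
representations through Fourier projections in each of 2 interaction
blocks, with a residual connection from the zero-filled input.  Whatever
the backbone — an image-domain-only UNet is registered under `"unet"` for
the backbone-swap comparison — the module ends with a hard data-consistency
projection: predicted k-space is replaced by the measured values wherever
the mask sampled.  Every reconstruction therefore reproduces the
measurements exactly (to float tolerance), which the tests assert.

**Segmentation (SSM).**  A UNet-style encoder–decoder with skip
connections and a per-pixel softmax over $K+1$ classes: background (0),
$K-1$ tissues, and an appended edge class.  Edge and
foreground/background labels act as auxiliary supervision that pushes the
sampler towards semantically informative measurements.  The same weights
serve the coarse and fine segmentation calls.  The SSM is pretrained on
fully sampled images and frozen thereafter.

**Semantic interaction (SIM).**  A residual refiner whose normalization
layers are spatially adaptive: at three scales, per-pixel scale and shift
are predicted from the (softmax, hence differentiable) segmentation stack
and applied to instance-normalized features.  The output head is
zero-initialized, so the module is exactly the identity before training —
`fine = coarse` at initialization, an invariant the tests check.  The fine
image feeds back to the sampler as its semantic-prior channel.

## Loss and training strategy

The hybrid loss is $L = L_{cr} + \lambda_1 L_{seg} + \lambda_2 L_{fr}$:
coarse and fine squared-L2 reconstruction terms and the cross-entropy of
both segmentation heads, averaged over the $P$ iterations.  Both heads are
supervised because both the coarse and the fine segmentation calls must
stay trained; the per-iteration average keeps the magnitude
independent of $P$.  Training is progressive: stage 1 freezes the
pretrained SSM and trains MSM+SFRM; stage 2 freezes everything except SIM;
stage 3 jointly trains MSM+SIM (SFRM stays frozen, reading the strategy
literally).  Frozen parameters are verified bit-identical across their
stage.  The published operating point ($\lambda_1 = 10^{-1}$,
$\lambda_2 = 10^{10}$, Adam at $5\times10^{-4}$, batch 12, three
3000-step stages, ±10° rotation augmentation) is available as
`fsl_config(preset = "published")`; note that $\lambda_2 = 10^{10}$ dwarfs
every other term — it is echoed verbatim with a warning.  The tiny preset
uses $\lambda_2 = 10^3$: with mean-reduced losses the cross-entropy term
is roughly two orders of magnitude larger than the squared-L2 terms, and a
unit fine-reconstruction weight lets the segmentation term dominate the
refiner, which then trades PSNR for segmentability; $\lambda_2 = 10^3$
keeps the refiner reconstruction-driven (the published
$\lambda_2 \gg \lambda_1$ at a numerically sane scale).

## What the synthetic phantoms emulate — and what they do not

`make_phantom()` produces piecewise-smooth magnitude images in $[0,1]$: a
dark background, a large deformed-ellipse body, and $K-2$ blob-shaped inner
tissues, modulated by a smooth ±8% bias field.  Tissue $k$ has mean
intensity $0.25 + 0.15(k-1)$ with ±0.03 per-phantom jitter: classes are
separated by at least ~0.09 in every phantom (unambiguous ground truth)
and consistent across phantoms (learnable class identity), mimicking how
real tissue contrast behaves across subjects.  Rician noise is simulated
exactly as magnitude noise: i.i.d. Gaussians on the real and imaginary
channels; $\sigma$ is expressed on the $[0,1]$ intensity scale.  Multicoil
data use Gaussian sensitivity lobes on a ring with linear phase ramps,
normalized so the per-pixel sum of squared magnitudes is 1, which makes
the root-sum-of-squares recombination exact.

What the phantoms do **not** emulate: anatomical texture and
fine-structure (real k-space energy decays more slowly), inter-subject
geometry statistics, partial-volume effects, or scanner-specific artifact
spectra.  A passing benchmark here shows the machinery — budgets,
gradients, orderings, trends — behaves as designed, not that the learned
trajectories would transfer to clinical data.

## Numerical choices

* **Fourier convention**: orthonormal, DC-centered FFT everywhere, so
  Parseval holds exactly and masks read naturally around the centre.
* **Budgets**: $n = \mathrm{round}(\alpha H W)$ for pointwise masks, ties
  rounded half away from zero.  Line-structured (1D Cartesian) masks
  quantize to whole lines, $n = H\,\mathrm{round}(\alpha W)$ — within one
  line of the pointwise budget, since whole-line acquisition cannot hit an
  arbitrary point count.  The centre preset takes 20% of the budget; the
  remainder is split evenly over the $P$ iterations (last takes the
  remainder).
* **Ties** in top-$n$ selection break by row-major index; line selection
  by lowest line index.
* **Complex data** travel as two real channels inside learned blocks;
  magnitude is taken only at module boundaries ($\sqrt{re^2+im^2+10^{-12}}$).
  The data-consistency projection is exact on the complex-valued
  reconstruction (`reconstruct_coarse(..., output = "complex")`); the
  magnitude discards phase, so the projection identity is checked on the
  complex output.
* **Cross-entropy** uses the softmax stack with a $10^{-12}$ floor inside
  the logarithm.
* **SSIM** uses a Gaussian window ($\sigma = 1.5$), size 7 below 128
  pixels and 11 above, evaluated where the window fits; PSNR uses a fixed
  data range of 1 on normalized images; Dice scores the anatomical classes
  $1..K-1$ and reports an empty-vs-empty class as 1.
* **Padding contract**: the UNet pads inputs bottom/right to a multiple of
  4 and crops the output, so any size ≥ the window works.
* **Degenerate inputs**: all-zero probability maps are rejected by the
  scaling layer; zero-energy targets are rejected by the normalized error
  map; infeasible budgets (fewer free points/lines than iterations) raise
  errors before training starts.

## The engine

No deep-learning runtime ships with this package's dependency set, and the
differentiable acquisition loop is precisely the point, so `fslmri` carries
a small reverse-mode autodiff engine: arrays with channels last, explicit
backward closures per operation, and convolution as fused im2col + BLAS
GEMM kernels in C (the adjoint of a same-padding convolution is computed
as a convolution with the flipped, channel-transposed kernel — no
scatter).  Every operator's gradient is tested against central finite
differences.  The unitary FFT's backward pass is the inverse FFT.  Adam is
the only optimizer.

## Desk-scale benchmark sizes

The bundled benchmark (acceptance tests and `scripts/acceptance.R`) uses
64×64 phantoms with $K = 4$ classes, 300 samples (250 train / 50 test),
$\alpha = 0.10$, 2D pointwise trajectories, $P = 3$, batch 2, Adam at
$2\times10^{-3}$, 600 SSM-pretraining steps and stage steps
(100, 70, 70); rotation augmentation is off at this scale so the short
runs spend their updates on the clean objective.  The standalone
reproduction script uses 150 training / 30 test phantoms with the same
stage sizes.  Networks use leaky rectifications (slope 0.1); with plain
rectifications, short low-batch runs intermittently lose whole output
classes to dead units.  These sizes are the
package's desk-scale operating point: large enough for the paradigm
orderings (learned vs fixed trajectories, with vs without semantic
guidance) and the iteration/robustness trends to emerge, small enough to
train on one CPU in minutes.  The robustness sweep evaluates the first 20
test phantoms at $\sigma \in \{0, 0.5, 1.0, 1.5, 2.0\}$.

## Known limitations

* The networks are an order of magnitude narrower than production
  reconstruction models; absolute PSNR/DSC values are not comparable to
  GPU-scale results, only orderings and trends are meaningful.
* Non-Cartesian (radial/spiral) trajectories, gridding/NUFFT, multicoil
  *reconstruction* (coil data are recombined to magnitude before entering
  the pipeline), adversarial/perceptual losses and 3D phantoms are out of
  scope.
* The straight-through estimator biases sampler gradients (as it does in
  any hard-selection scheme); the Monte-Carlo score subtraction mitigates
  but does not remove this.
* With batch 2 and ~100-step stages the paradigm orderings hold in the
  mean over 50 held-out phantoms but individual runs are noisy; seeds are
  fixed throughout.
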