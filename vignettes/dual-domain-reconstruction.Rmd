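---
title: "Dual-domain cascaded reconstruction of undersampled multi-coil cardiac MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-domain cascaded reconstruction of undersampled multi-coil cardiac MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The reconstruction problem

Accelerated Cartesian MRI acquires only a subset of phase-encode lines of
k-space. With `E` the line-sampling operator, `F` the 2-D Fourier transform
and `S_i` the complex sensitivity map of receiver coil `i`, the measurements
are `x_i = E F (S_i m)` for the underlying composite image `m`. Recovering
`m` from the zero-filled data is ill-posed: the missing lines alias along the
phase-encode direction.

`mricascade` implements three families of reconstructors behind one common
simulation and evaluation harness:

* **zero-filled**: inverse transform of the zero-filled coil k-space followed
  by matched-filter ("adaptive") coil combination — the floor every method
  must beat;
* **CS-MRI**: the L1-regularized least-squares problem
  `argmin_m 1/2 Σ_i ||E F(S_i m) − x_i||² + λ ||W m||₁` with `W` an
  orthonormal db4 wavelet transform, solved by ISTA;
* **learned dual-domain cascades**: two small U-Nets, one operating on
  composite k-space (K-Net) and one on composite images (I-Net), cascaded in
  either order (KI or IK) and interleaved with a multi-coil data-consistency
  (MCDC) operation, plus a single-domain image U-Net baseline without any
  data consistency.

All k-space/image conversions go through one centered, unitary transform pair
(`fft2c()`/`ifft2c()`, DC at index `floor(n/2)+1`), so data-consistency
identities hold exactly across modules. The phase-encode axis is the second
array axis throughout.

## The MCDC operation, and what it does (and does not) guarantee

`mcdc(composite, maps, acquired)` projects a composite image through the coil
model and back: multiply by each `S_i`, transform to k-space, hard-replace
the sampled lines with the measured values, transform back, and recombine
with `Σ_i conj(S_i)·`. Because the maps are normalized to unit root sum of
squares, the expansion `E: m -> {F(S_i m)}` is an isometry and the combine is
its adjoint.

Two properties are exact and tested at machine precision: under **full
sampling** the operator returns the reference regardless of its input, and
under an **empty mask** it is the identity. Every element of the consistency
set `{m : E F(S_i m) = x_i}` is an exact fixed point.

One property commonly attributed to data-consistency layers does **not** hold
for this composite-image form: the single pass is not a projection. Writing
`R = E^H M E` (with `M` the line mask), the pass is `P(x) = x − R(x − m)`;
`R` is positive semi-definite with spectrum in `[0, 1]` but is not idempotent,
because line masking does not commute with the coil-subspace projector
`E E^H`. Consequently `P(P(x)) ≠ P(x)` (deviations of order 1e-2 on 64×64,
8-coil fixtures) and the k-space of the recombined output no longer matches
the measurements exactly at sampled positions (same order). `P` is an
averaged operator: iterating it contracts monotonically toward the
consistency set, and the package tests exactly that — the iterate movement
and the sampled-sample residual both decrease monotonically — rather than a
projection identity the operator does not have. Reconstruction quality is
unaffected by this distinction (the final MCDC still pulls the estimate
toward the measured data); it only matters for what may be asserted about
exactness.

## Network architecture

Both subnetworks are the same small U-Net operating on 2-channel real
tensors (channel 1 = real part, channel 2 = imaginary part):

* `4·depth + 2` convolution layers of size 3×3 (default depth 2 → 10),
  each followed by ReLU then batch normalization; distributed 2 per encoder
  level, 2 in the bottleneck, and 2 per decoder level (the first decoder
  convolution of each level directly follows the 2× nearest-neighbour
  upsampling);
* 2×2 max pooling per encoder level, skip concatenation per decoder level;
* a final 1×1 convolution followed by batch normalization, no activation;
* no bias terms anywhere; weights drawn from `Normal(0, 0.05²)`.

Feature widths double per level from `base_filters` (64 by default; 8 in the
desk-scale experiments, where the full-width network would be severely
over-parameterized for 64×64 phantoms).

Two declared choices deserve justification:

* **Per-example normalization.** Each network input is scaled to unit
  maximum magnitude before packing and the scale reapplied on output.
  K-space has an enormous dynamic range (the DC line dominates); without a
  per-example scale the k-domain loss is numerically ill-conditioned.
* **Global residual connection** (`unet_config(residual = TRUE)`, default).
  The network output is added to its input, and the scale (gamma) of the
  final batch normalization is initialized to zero, so every network starts
  as the exact identity — the standard initialization for residual branches.
  Without this, the final batch normalization pins the output to unit
  variance per channel while the required correction is two orders of
  magnitude smaller, and most of a short training run is spent shrinking one
  scalar. The non-residual form is available (`residual = FALSE`) and is
  exercised in the tests.

## Training recipe

Both cascade orders train **incrementally**: stage 1 trains the first
subnetwork alone against fully sampled labels in its own domain (K-Net:
composite zero-filled k-space → fully sampled composite k-space; I-Net:
zero-filled image → fully sampled image). Stage 2 freezes stage 1, pushes
every example through it plus MCDC (and the FFT/IFFT the order requires), and
trains the second subnetwork on those corrected inputs. There is no joint
fine-tuning.

The optimizer is RMSProp (decay 0.9, epsilon 1e-7) with mean-squared-error
loss, initial learning rate 0.001 reduced by 0.1 after 10 consecutive epochs
without validation improvement, and early stopping after 20 stale epochs
(best-validation weights restored). The 80/20 train/validation split is drawn
**by volume**, never by frame, so temporally adjacent frames of one simulated
cine cannot straddle the split. Every history records the learning rate in
force per epoch; `expected_lr_trace()` replays the plateau rule over the
logged validation losses so a training log can be audited after the fact.

During training MCDC uses the true simulation maps; at inference the maps can
instead be self-calibrated from the fully sampled center band
(`center_calibrated_maps()`), which is the realistic condition when no ground
truth exists.

## Synthetic data

`make_phantom()` draws a cardiac-like scene from jittered ellipses: an
elliptical torso with a brighter chest-wall rim, a bright left-ventricular
blood pool inside a darker myocardial ring, a right-ventricle-like pool, and
small internal structures; magnitudes lie in [0, 1] and the background is
exactly zero. A smooth second-order polynomial phase with seed-drawn
coefficients makes the real/imaginary channels non-trivial. The modified
Shepp-Logan phantom is available as a second, independently checkable
reference object. Every generator output is a pure function of
`(seed, shape, kind)`; no global RNG state is consumed.

Coil sensitivities come from a discretized Biot-Savart integral (64 straight
segments per loop) for `n_coils` circular loops placed uniformly on a ring of
radius `0.6·nx` pixels with loop radius `0.25·nx`, in planes parallel to the
image at a standoff of half the loop radius (keeping the field finite
everywhere, including for loop centers inside the field of view). The
rotating-frame receive field `Bx − i·By` gives each raw map a smooth
magnitude and phase; the stack is then normalized to unit root sum of
squares per pixel. These geometric defaults are declared conventions for a
simulated array, not values inferred from data.

Undersampling masks sample exactly `round(ny/AF)` phase-encode lines: a fully
sampled center band (fraction 1/16 of lines by default — this is also the
self-calibration region Walsh estimation needs) plus outer lines drawn
without replacement with probability proportional to a DC-centered Gaussian
of width `0.15·ny`. Exact line counting makes the achieved acceleration
reproducible; Bernoulli per-line sampling would not.

What the generator does **not** emulate: cardiac or respiratory motion
between frames (frames are independent re-draws, not a beating heart),
k-space noise, non-Cartesian trajectories, and the anatomical variability of
real cohorts. Passing the desk-scale learning tests therefore demonstrates
that the cascades, data consistency and training loop work as designed — not
that the trained weights transfer to clinical data.

## Walsh sensitivity estimation

`walsh_maps()` forms, per pixel, the local correlation matrix of the coil
images over a `block × block` neighborhood and takes its principal
eigenvector (vectorized power iteration initialized from the center coil
vector), phase-referenced to coil 1 and normalized to unit RSS. On
noise-free data the single-pixel block is exact (the coil vector itself spans
the rank-1 correlation). Block averaging — which exists to stabilize the
estimate under noise — biases the eigenvector wherever the maps or the image
intensity vary across the block: with the default 7×7 block at 64×64 the
median magnitude error against the true maps is ~3e-3 but reaches ~0.2 near
intensity edges and the image boundary. This bias is a property of the
estimator, not an implementation artifact, and is pinned by a unit test.

## CS baseline numerics

ISTA on `f(m) = 1/2 Σ_i ||E F(S_i m) − x_i||²` has a 1-Lipschitz gradient
under unit-RSS maps, so any step `≤ 1` (default 1) guarantees a monotone
objective; the soft-threshold level is `step·λ`. The sparsity transform is a
periodized orthonormal db4 wavelet at 3 levels, implemented directly (no R
wavelet package exists in the dependency set); orthonormality and perfect
reconstruction are tested to machine precision. The default `λ = 1e-3` is
tuned per experiment on a 5-point grid spanning 1e-4 to 1e-2 using phantoms
disjoint from the test set. A finite-difference (total-variation-like)
sparsity option was considered and rejected: its proximal operator has no
closed form, so an ISTA iteration would lose the monotonicity guarantee that
makes this baseline easy to validate.

## Metrics

SSIM, PSNR and RMSE are computed on magnitude images after normalizing both
test and reference by the reference maximum. SSIM uses the canonical Wang
parameters (11×11 Gaussian window, sigma 1.5, K1 = 0.01, K2 = 0.03, dynamic
range 1) with valid-window aggregation, and is pinned against an independent
NumPy implementation on frozen fixtures. PSNR is `20·log10(1/RMSE)` after
normalization; exact reconstructions report `Inf` and are excluded from
summary means with a warning. The reference image is always the adaptive
combination of the fully sampled coil images — the same definition the
reconstruction pipeline uses — never the raw phantom.

## Problem sizes used by the shipped experiments

The package's own experiments (test suite and `scripts/acceptance.R`) run at
64×64 with 8 coils and `base_filters = 8`: 200 phantom frames (20 volumes ×
10 frames) with up to 30 epochs per stage for the learning property test, and
100 training frames / 30 held-out test frames with 20 epochs per stage for
the end-to-end method comparison. These sizes were chosen so a complete
two-stage training runs in minutes on one CPU core while still leaving a
clear margin between the learned cascades and the zero-filled floor. At this
scale the expected orderings `cascade > zero-filled` and `CS > zero-filled`
are robust; the finer orderings between IK, KI and CS reported at full scale
on real cardiac data are logged by the acceptance script but not asserted,
since they depend on training volume and tuning budgets far beyond a
desk-scale run.

## Known limitations

* The composite-image MCDC is a contraction, not a projection (see above);
  per-coil k-space fidelity after recombination is approximate by
  construction.
* Training runs on composite (coil-combined) data; the cascades are agnostic
  to coil count at inference (verified at 4 and 12 coils for an 8-coil
  training), but no claim is made about transfer across field strengths,
  anatomies or noise levels.
* One mask per volume by default (`mask_per_frame = TRUE` available); mask
  variation across frames of a subject is otherwise not modelled.
* The HDF5 container stores complex arrays as paired `real`/`imag` float
  datasets, since HDF5 has no native complex type.
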