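---
title: "MAP reconstruction of CT volumes with a 3D normalizing-flow prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MAP reconstruction of CT volumes with a 3D normalizing-flow prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ultra-sparse-view CT asks for a full 3D volume from one or two 2D projection
images — an observation operator that discards almost all of the information.
`flowct` treats this as maximum-a-posteriori (MAP) estimation: the
reconstruction maximizes `log p(y | x) + log p(x)`, where the likelihood term
rewards projection consistency and the prior `p(x)` is a generative model of
chest CT volumes learned beforehand. Because the prior is a normalizing flow,
`log p(x)` is exact (not a bound), and the search can run in the flow's latent
space, where every point decodes to a plausible volume.

## The flow prior

The prior is a multi-scale invertible network in three spatial dimensions.
Per level:

1. **squeeze** — each even spatial axis is halved and the sub-voxel offsets
   become channels (×8 for a cube), trading resolution for channel depth;
2. `depth` **flow steps**, each an *actnorm* (per-channel affine with
   data-dependent initialization), an *invertible 1×1×1 convolution* (a
   learned channel mixing with tractable determinant), and an *affine
   coupling* that transforms half the channels with a scale and shift
   computed from the other half by a small 3-layer convolutional network
   (3³, 1³, 3³ kernels, final layer zero-initialized so the flow starts near
   the identity);
3. a **split** that factors out half the channels as that level's latent
   block under a learned diagonal Gaussian. The top level keeps its whole
   tensor (the "learn-top" prior).

The coupling scale is `sigmoid(raw + 2) + eps` with `eps = 1e-3`: bounded in
`(eps, 1 + eps]`, so inversion can never divide by zero and the
log-determinant is always finite. Exact log-likelihood follows from the
change of variables, `log p(x) = log p(z) + log |det df/dx|`, with every
layer's log-determinant available in closed form. Sampling draws
`z ~ N(mu, T² Sigma²)` per level and decodes; the temperature `T` trades
diversity for typicality, and `T = 0` returns the decoded prior mean.

Design notes where the architecture was open:

* The 1×1×1 convolution stores a dense `C×C` matrix and takes determinants
  and inverses directly; at the channel counts used here (≤ 512) this costs
  microseconds and avoids the bookkeeping of an LU parameterization.
* Actnorm layers are included even though a minimal description of the
  architecture needs only the permutation and coupling: they stabilize early
  training, and their data-dependent initialization (unit variance per
  channel on the first batch) is what makes the first NLL evaluations finite
  at low bit depths.
* The squeeze halves only axes that are even, so degenerate shapes such as
  `1×1×2` remain usable for closed-form checks (density normalization by
  quadrature).

## Progressive training

Training minimizes the mean NLL with Adam (linear warmup to a steady rate)
over stages of increasing bit depth: the volumes are quantized to 2, 3, 4,
then 8 bits (floor-division binning), uniformly dequantized, and mapped to
`[0, 1)`. Early stages present a far simpler target density — in effect a
coarse histogram of the anatomy — which moves the bulk of the parameters into
place cheaply; later stages refine detail. Each stage warm-starts from the
previous stage's best validation checkpoint; the optimizer state is reset
because the objective changes with the bit depth. Validation NLL is monitored
every epoch (without dequantization noise) and the stage returns the best
checkpoint seen, with patience-based early stopping.

The full-scale recipe (`progressive_schedule()` defaults) is stages
(2 bits, 96 epochs), (3, 324), (4, 24), (8, 144), steady rate `1e-4`,
minibatch 1 per device. The desk-scale recipe (`desk_schedule()`) uses a few
epochs per stage, steady rate `1e-3` and minibatch 2–4: with only a few
hundred optimizer steps in total, a `1e-4` rate cannot leave initialization,
so the desk rate is deliberately larger. Gradients are clipped at a global
norm of 100.

## The observation model

A projection is the mean over one axis: coronal views average depth,
sagittal views average width (`project()`). The operator is linear and
mean-preserving; it is a deliberate idealization of a radiograph (no
attenuation physics, spectra or scatter). The ultra-low-dose protocol is
emulated by adding i.i.d. `N(0, sigma² = 100)` noise per pixel on the 8-bit
gray scale (`add_noise()`).

## MAP reconstruction in latent space

With Gaussian observation noise, the posterior objective per volume is

```
E(z) = sum_j ||y_j - P_j G(z)||² / (2 sigma²)  -  Tb² · log p_theta(G(z)),
```

where `G` is the flow decoder, the sum runs over the input views
(independent Gaussian likelihoods per view), and
`Tb² = 1 / (log 2 · D·H·W)` rescales the log-likelihood to bits per voxel so
its weight is comparable across resolutions. Descent runs on `z` with the
model frozen:

```
z <- z - alpha(n) * grad_z E,   alpha(n) = A (1 - exp(-0.01 n)),
```

with `A = 0.9` for the ultra-low-dose protocol. For the standard (noiseless)
protocol the limit `sigma² -> 0` is taken: the prior term vanishes and the
`sigma²` in `A = 0.2 sigma²` cancels the `1/sigma²` in the cycle term,
leaving plain descent on `0.5 Σ ||y_j - P_j G(z)||²` with effective amplitude
0.2. The initial guess is a temperature-0.5 prior sample. Note that the
`Tb²` weighting makes the prior term's per-iteration gradient small relative
to the cycle term; the prior acts mostly through the initialization and by
keeping the trajectory near the decoder's data manifold, which is also why
the noisy-input runs do not overfit the noise (their residual stalls at the
noise floor, far above the noiseless stopping threshold).

**Intensity-scale convention.** The stopping threshold
`tau² · N · H2D · W2D` (default `tau = 3`) is meaningful only on the 0–255
gray scale (an RMS of 3 gray levels per pixel). The descent itself, however,
runs on the model's unit `[0, 1]` scale with `sigma²` entering as the
dimensionless number 100. This is a deliberate pairing: if the cycle term
were formed on the 0–255 scale, the printed amplitudes (0.2 and 0.9) would
put plain gradient descent far beyond its stability limit for any decoder
whose projected Jacobian has order-one singular values (the step–curvature
product scales with 255²); on the unit scale both amplitudes sit in the
stable range. `flowct` therefore optimizes on the unit scale and converts the
residual to 8-bit units only for the stopping rule and for reporting. The
`sigma² -> 0` equivalence between the two protocols is preserved exactly and
is property-tested.

**Stopping.** Three rules, whichever fires first:

* *residual-met* — summed squared 8-bit residual ≤ `tau² · Σ_j n_pixels_j`;
* *n_max* — iteration budget (default 1000) exhausted;
* *latent-converged* — one step moves `z` by less than `1e-4` times the
  trajectory's total displacement from the initial guess, and at least 100
  iterations have run (the `alpha` ramp makes early steps vanishingly
  small). The displacement normalization matters: normalizing by `||z||`
  instead declares convergence while the residual is still descending
  steadily, because the optimum is typically only a small relative
  perturbation of the initial sample.

One latent trajectory is used per reconstruction; restarts are available as
an option (`init_z`) but are off by default. Both protocols initialize at
temperature 0.5 (the noiseless protocol's convention is simply reused for
the noisy one), and the residual threshold is applied to the residual summed
over views — `tau² · Σ_j n_pixels_j` — rather than per view, matching the
product form of the bound with the view count.

## The phantom population

Real cohort data cannot ship with the package, so `phantom_spec()` defines a
synthetic population of chest-like volumes: a soft-tissue body ellipsoid,
two low-intensity lungs, a heart sphere, a spine cylinder and a flat bed
slab near the posterior face (the bed being a reliably reconstructable
landmark), smoothed with a 0.8-voxel Gaussian kernel. Per-subject uniform
jitter (±0.04 in normalized position, ±8 % in size, ±8 gray levels in
intensity) gives the population genuine variability with shared structure,
which is exactly what a generative prior needs to be learnable: one scan per
subject, split 384:32:34 into train/validation/test in the style of a
450-subject cohort.

What the phantoms do *not* emulate: fine bronchovascular texture,
pathology, attenuation physics, scanner artifacts, or inter-subject
anatomical topology changes. Tests passing on phantoms therefore demonstrate
the *mechanics* of the method — exact likelihoods, stable inversion,
projection-consistent descent, the benefit of a second view, robustness to
the stated noise level — not clinical image quality.

## Problem sizes used by the tests and the acceptance script

The package expresses the full-scale configuration (128³ volumes, 5 levels,
depth 8, width 512; `flow_config_full()`), but the shipped tests run a
desk-scale study chosen to keep a complete train-and-reconstruct cycle on a
single CPU comfortable: 200 phantoms at 16³, a flow with 3 levels, depth 3,
width 48, progressive stages (2,2), (3,2), (4,3), (8,25), and five held-out
subjects reconstructed under both protocols with one and two views. Layer
and Jacobian checks run at 4³ where the full Jacobian is cheap to form by
finite differences; density normalization runs on a 1×1×2 toy configuration
where quadrature over the plane is exact to plotting accuracy.

## Numerical choices

* Quantization between progressive stages is floor-division binning
  (rounding would also be defensible; flooring matches the convention that
  bin `k` covers `[k, k+1)` and keeps `to_model_space()` a pure affine map);
  dequantization noise is uniform in the bin and applied during training
  only (validation NLL and reconstruction use bin midpoints), the standard
  exact-likelihood convention.
* `eps = 1e-3` in the coupling scale bounds every scale in `(1e-3, 1.001]`;
  together with the dense 1×1×1 parameterization this makes the
  reconstruction backward pass free of divisions by learned quantities that
  can vanish.
* PSNR of identical volumes is reported as a 100 dB cap rather than `Inf`
  so reports serialize cleanly; SSIM uses uniform 7³ windows, `K1 = 0.01`,
  `K2 = 0.03`, data range 1, over fully-interior windows only; NRMSE is
  normalized by the reference volume's intensity range and is undefined
  (an error) for constant references; reported variances are population
  variances.
* Degenerate inputs fail loudly: all-air HU volumes (max ≤ −1000), shape
  mismatches, duplicate views, non-finite losses (training aborts with the
  last finite checkpoint), non-finite latent gradients (error naming the
  iteration).

## Known limitations

* The depth-averaging projector is linear and noise is additive Gaussian;
  real low-dose radiographs have Poisson-family noise and nonlinear
  attenuation. The reconstruction machinery only needs a differentiable
  operator, so replacing `project()` is straightforward, but nothing else
  in the package models physics.
* The latent descent is first-order with a fixed schedule; badly
  conditioned directions (fine image detail under a mean projector)
  converge slowly, which is why the residual stopping rule, not exact
  optimality, defines termination.
* The phantom population is low-dimensional; bits-per-dim values on it are
  far lower (more negative) than anything achievable on real CT, and
  metric magnitudes are not comparable to cohort studies on hospital data.
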