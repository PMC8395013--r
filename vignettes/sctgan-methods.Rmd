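---
title: "Synthetic CT from CBCT: models, simulation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic CT from CBCT: models, simulation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctgan)
```

## The problem

Cone-beam CT (CBCT) acquired in the treatment room carries scatter-induced
artifacts — shading, cupping, beam-hardening, reduced contrast — and its pixel
values are not calibrated Hounsfield units (HU), so it cannot be used directly
for dose calculation or quantitative soft-tissue assessment. `sctgan`
implements image-to-image translation from CBCT to a synthetic CT (sCT) with
CT-like HU, in two training regimes sharing one generator architecture:

* **supervised** — paired, registered CBCT/CT slices, pixel-wise L1 loss;
* **unsupervised** — unpaired pools, a cycle-consistent adversarial objective
  (two generators, two PatchGAN discriminators; adversarial + cycle +
  identity terms).

Everything runs on the CPU: the package carries its own small convolution
engine (im2col + GEMM in single precision for 3×3/4×4 kernels, FFT-domain
convolution for the large inception kernels, where the cost per branch is
independent of kernel size).

## The phantom simulator

Real paired pelvic data cannot ship with a package, so `generate_phantom()` /
`generate_dataset()` synthesize the study conditions: an elliptical
soft-tissue body on an air background, elliptical high-density bone
structures, an optional gas cavity in the posterior body half (rectal gas),
and Gaussian within-tissue texture. `apply_cbct_artifacts()` then degrades a
CT slice into its CBCT partner with the additive radial field

$$\mathrm{CBCT}(x) = g\,\mathrm{CT}(x) + o
  - A\left(1 - (r/R)^2\right) + B\,(r/R)^p + \varepsilon(x),$$

inside the body, where $r$ is the distance from the body centroid and $R$ the
body's effective radius (mean of the mask's principal semi-axes — well
defined for ellipses and irregular masks alike). The five interpretable
parameters cover the canonical CBCT degradations: linear HU miscalibration
($g$, $o$), scatter cupping ($A$, a depression of $A$ HU at the centre
fading to zero at the rim), beam-hardening brightening at the periphery
($B$, exponent $p$), and additive Gaussian noise
$\varepsilon \sim N(0, \sigma^2)$. Field-of-view truncation, an integer-pixel
isocenter shift, and an independent re-draw of the gas cavity (anatomical
mismatch between the two acquisition days) complete the model. All outputs
are clipped to the working HU range $[-1024, 3200]$.

Default magnitudes (`default_model_ranges()`): cupping 20–120 HU, offsets
±80 HU, gain within ~10 % of unity, noise 5–25 HU — plausible pelvic-CBCT
scales chosen once for this simulator; the reference literature reports no
quantitative artifact magnitudes to reproduce. Per *subject*, one phantom
spec and one artifact model are drawn; slices within a subject vary
anatomically under slice-level sub-seeds derived from
(seed, subject, slice), so a subject's content does not depend on dataset
size. Every operation is a pure function of its inputs and seed.

**What the simulator does not emulate:** projection-domain physics (no
Monte-Carlo transport, no cone-beam reconstruction), spatially correlated
anatomy texture (the within-tissue texture is i.i.d. Gaussian per pixel),
streak/motion artifacts, and multi-organ soft-tissue contrast. Tests passing
on phantoms therefore validate the *mechanics* of the pipeline — masking,
alignment, losses, optimization, metrics, fold hygiene — not clinical image
quality. The i.i.d. texture in particular makes the translation task
*harder* than real anatomy in one specific way: texture detail shared by the
pair must pass through the network pixel-exactly to reach baseline MAE,
which penalizes any smoothing; see "Convergence behaviour" below.

## Pre-processing

`compute_body_mask()` follows the standard masking recipe: Otsu's threshold
computed once per volume (not per slice, so slices share one threshold),
then per slice the largest connected component (removing couch and debris),
binary hole filling (gas cavities remain inside the body), and one 3×3
erosion to trim the partial-volume halo. The erosion element size is not
dictated by the recipe; one 3×3 pass only removes the boundary ring.
Masked-out pixels are set to −1000 HU (air) — anatomically meaningful and
distinct from the clip floor of −1024; the value is a documented argument.

Alignment uses the isocenter offsets carried by the paired data:
integer-pixel translation after mm→pixel conversion, vacated pixels filled
with air, no interpolation (avoids resampling blur; offsets are rigid
translations). Intensities are clipped to $[-1024, 3200]$ and mapped
linearly to $[0, 1]$ (`normalize_hu()`; the exact inverse is
`denormalize_hu()`). Slices are resampled bilinearly to the network size
(256×256 in the reference protocol; the desk-scale examples in this package
use 64×64, which divides by $2^4$ as the 5-level generator requires).
Augmentation (`augment_pair()`) applies one of the eight
rotation-by-90°×horizontal-flip configurations coherently to both members of
a pair, re-sampled each epoch.

## Networks

The **ConvBlock** is convolution → instance normalization (learned
per-channel scale and shift, computed per sample over spatial positions) →
swish ($x\,\sigma(x)$). Convolutions inside normalized blocks carry no bias:
the normalization immediately discards any input mean, and its learned shift
plays the bias's role. This convention is not cosmetic — it is the unique
convention under which the discriminator's printed trainable-parameter total
can be reproduced exactly (see below), and it matches common practice for
normalized convolutions. The **InceptionBlock** runs four parallel
ConvBlocks with kernels 1/5/7/11 and equal widths and concatenates them,
giving the upper network levels multi-scale receptive fields.

The **generator** is a five-level U-Net whose two upper levels (full and
half resolution) are InceptionBlocks and whose three deeper levels are 3×3
ConvBlocks; contraction by 2×2 max pooling, expansion by nearest-neighbour
upsampling followed by skip concatenation and the mirrored level's block; a
final 3×3 convolution + sigmoid yields one output channel in $[0,1]$. The
**discriminator** is a PatchGAN: four 4×4 ConvBlocks with strides 2/2/2/1
(the first without normalization, per PatchGAN convention), then a 4×4
convolution + sigmoid producing a patch map (32×32 for 256×256 input) that
classifies overlapping patches real/fake.

**Channel widths.** The architecture's authoritative anchors are its
trainable-parameter totals: 2,554,977 (generator) and 429,185
(discriminator), i.e. 5,968,324 for the two-generator/two-discriminator
ensemble. The discriminator total pins its layout almost uniquely: base
width 32 (32/64/128/128), bias-free convolutions, affine normalization on
blocks 2–4, and a biased 4×4 head — no configuration with convolution biases
inside normalized blocks reaches the printed total. The generator total
still admits many integer layouts; the package uses widths
(16, 28, 92, 208, 400), selected once among the exact solutions for its
moderate width at the two (computationally dominant) full/half-resolution
inception levels, which keeps CPU training runs tractable. Both totals are
asserted exactly in the test suite, and `count_trainable_parameters()`
counts every learnable tensor (kernels, biases, normalization scale/shift).

Weights initialize as $N(0, 0.02)$ (the GAN convention), normalization scale
1 and shift 0, biases 0, all under a supplied seed; two builds from the same
seed are bit-identical.

## Training

Both routines follow one protocol: ADAM with learning rate $2\times10^{-4}$,
$\beta_1 = 0.5$, $\beta_2 = 0.999$ (and $\epsilon = 10^{-8}$), batch size 10,
coherent augmentation re-drawn each epoch, subject-level train/validation
split, and checkpointing of the weights achieving maximal validation SSIM
(computed over the validation pool each epoch).

The supervised objective is the mean absolute pixel difference between
generated sCT and ground-truth CT on the normalized scale. The unsupervised
objective combines, with the adversarial weight fixed at 1:

* adversarial terms: binary cross-entropy of each discriminator's patch map
  against label 1 (for generator updates) or the real/fake labels 1/0 (for
  discriminator updates); fakes are detached from generator updates, and a
  least-squares variant is available behind `adversarial = "lsgan"`;
* cycle consistency: $\lambda_{cyc}\,[\,L_1(G_{CBCT}(G_{CT}(CBCT)), CBCT) +
  L_1(G_{CT}(G_{CBCT}(CT)), CT)\,]$;
* identity terms: $\lambda_{id}\,[\,L_1(G_{CT}(CT), CT) +
  L_1(G_{CBCT}(CBCT), CBCT)\,]$.

$\lambda_{cyc} = 10$ and $\lambda_{id} = 5$ are the canonical
cycle-consistent-GAN defaults; both are exposed in `train_config()`. No
discriminator image-history buffer is used (available as a future config
extension). BCE inputs are clamped away from $\{0,1\}$ by $10^{-7}$; the
gradient is propagated through the sigmoid so saturated patch maps give
bounded, not exploding, updates. Discriminator and generator parameters are
strictly isolated: computing the adversarial input-gradient for the
generators snapshots and restores the discriminator's gradient buffers.

### Convergence behaviour at desk scale

Two properties of this setting deserve explicit statement, because they
bound what small demonstration runs can show.

First, the *rate* of output-level change is set by the optimizer protocol.
With ADAM at learning rate $2\times10^{-4}$, a sign-consistent error moves
each parameter by about the learning rate per step, which moves the
generator's output logit by roughly $10^{-2}$ per step early in training. An
$N(0, 0.02)$-initialized sigmoid-output network starts near 0.5 (≈1100 HU
away from soft tissue), so closing the gap to tens of HU requires on the
order of $10^3$ update steps — consistent with the reference protocol
(thousands of steps over 25 epochs). A 5-epoch run over 200 slices (80
steps) reduces validation MAE several-fold but necessarily remains far from
convergence; in our runs, 25 epochs on 200 phantom slices took validation
MAE from ≈1100 HU to ≈75 HU with SSIM still rising.

Second, the phantom's i.i.d. per-pixel texture (σ = 20 HU) plus acquisition
noise (σ = 10 HU) imposes an *irreducible floor*: reproducing white-noise
texture exactly through an encoder–decoder is only possible via the skip
connections, and separating it from the CBCT's own additive noise is not
possible at all, so baseline-level MAE (≈22 HU under the demonstration
corruption) is close to the best any translator can do on this simulator.
Real anatomy, whose texture is spatially correlated, does not share this
pathology.

The adversarial routine additionally shows the classic small-data GAN
failure mode at desk scale: the discriminator wins quickly (its loss falls
toward zero), the generators' adversarial terms saturate, and validation MAE
does not improve within a handful of epochs. These behaviours are documented
rather than hidden: the acceptance tests run the scaled-down recovery
experiments exactly as configured and report what they measure.

## Evaluation

`compute_mae_hu()` evaluates on denormalized HU images over the body mask by
default (evaluating air rewards nothing; a whole-frame mode exists);
`compute_psnr()` uses data range 1.0 on the normalized scale (equivalently
4224 HU — PSNR is range-dependent, so the range is part of the definition and
documented), returning `Inf` for identical images; `compute_ssim()` is the
Wang mean-SSIM with an 11×11 Gaussian window, σ 1.5, $K_1 = 0.01$,
$K_2 = 0.03$, valid-mode windows. The test suite checks both SSIM and PSNR
against independent brute-force implementations to $10^{-6}$ on random
images.

Cross-validation (`make_folds()`, `cross_validate()`) is strictly
subject-level: subjects are shuffled under a seed and dealt round-robin into
k near-equal folds; a leakage guard asserts that no training subject appears
in any held-out fold. Aggregation is median (interquartile range), and
`compare_models()` applies the tie-corrected Kruskal–Wallis test per metric
with Tukey–Kramer-type post-hoc comparisons on mean ranks (studentized-range
critical values with the Kramer correction for unequal group sizes) at
α = 0.01.

## Numerical choices and degenerate inputs

* Convolution padding is "same" with the extra pixel bottom/right for even
  kernels (4×4, stride 1: pad 1 top/left, 2 bottom/right).
* The FFT convolution path pads to the next even 5-smooth size ≥ H + k − 1,
  guaranteeing linear (not circular) convolution; kernels are transformed
  once per forward pass, and the backward pass reuses the cached spectra via
  the conjugate/phase identity for the 180°-rotated embedding. Agreement
  with the dense path is at single-precision level (~10⁻⁷ relative) and is
  asserted in the tests.
* Instance normalization uses ε = 10⁻⁵ inside the square root; an
  all-constant channel yields zero (not NaN) after normalization.
* `compute_body_mask()` refuses an all-constant volume (no Otsu threshold
  exists); `apply_mask()` and the metric functions reject shape mismatches
  and empty regions; `denormalize_hu()` rejects inputs outside [0, 1].
* Ties in 2×2 max pooling resolve to the first maximum in column-major
  order; the backward pass routes the gradient to exactly one argmax.
* `translate_volume()` refuses an explicitly uninitialized generator.

## Known limitations

* The simulator's additive radial artifact model reproduces profile shapes
  (cupping concavity, peripheral brightening) but not projection physics.
* Desk-scale training budgets demonstrate mechanics and direction of
  improvement, not converged clinical performance (see "Convergence
  behaviour").
* The unsupervised routine at small scale is sensitive to
  discriminator/generator balance; the LSGAN flag mitigates saturation but
  small-data adversarial training remains unstable by nature.
* Single-precision arithmetic in the convolution engine bounds gradient
  reproducibility at ~10⁻⁶ relative; loss histories are bit-reproducible
  across runs on the same build, which the tests assert.
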