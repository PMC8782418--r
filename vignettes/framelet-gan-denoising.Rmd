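---
title: "Unpaired wavelet-framelet GAN denoising of low-dose CT: models, choices, limits"
author: "waveganCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unpaired wavelet-framelet GAN denoising of low-dose CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic phantoms do and do not
emulate, the numerical choices, and the known limits.

## The translation problem

A low-dose abdominal CT slice (80 kVp class acquisition, filtered back
projection) differs from a standard-dose slice (120 kVp class) in two
coupled ways: it is noisier (image noise SD around 14 HU in muscle versus
around 11 HU), and its contrast-enhanced structures sit at higher CT
numbers, because the softer 80 kVp spectrum lies nearer the iodine K-edge
(portal vein ≈247 vs ≈188 HU; liver ≈146 vs ≈121 HU; muscle ≈76 vs
≈71 HU). A denoiser trained on paired scans is not an option — no patient
is scanned twice at two doses — so the model must learn the domain
translation from *unpaired* collections. The generator therefore has two
jobs at once: suppress noise and shift attenuation, while a pixel-wise
constraint keeps it from inventing or destroying anatomy.

## Networks

The generator is a deep convolutional framelet encoder–decoder. Per
contracting step: two zero-padded 3×3 convolutions, each followed by batch
normalization and a leaky ReLU; then single-level orthonormal 2-D Haar
analysis halves the resolution. The LL band continues downward; LH, HL and
HH are held for the matching expansive step, where Haar synthesis
recombines them with the decoder's low-pass features to upsample. The
synthesized features are concatenated with the same-step encoder features
and refined by two further convolution blocks; a 1×1 convolution emits the
output.

One sentence of the architecture's usual description is genuinely
ambiguous — what exactly "concatenates" and what "skips". We resolved it
as: the high-pass subbands skip into the synthesis (so fine detail
re-enters exactly where resolution is restored, and the transform pair
stays exactly invertible), and the concatenation joins the upsampled
features with the encoder features of the same step, as in any U-shaped
network. Any resolution of the ambiguity that keeps both a detail path and
a feature skip is functionally similar; this one keeps the wavelet pair
clean.

The discriminator is a patch classifier: four 4×4 stride-2 convolutions
(batch norm, leaky ReLU slope 0.2) plus a 1×1 convolution, producing a
spatial score map — 8×8 on a 128×128 patch, one score per receptive field.

Feature widths are configuration, not contract: the clinical-scale default
doubles from 64 per step, while desk-scale runs use 8–16. Output layers
(the 1×1 convolutions) carry no normalization: normalizing the final
regression output would fight the loss, and a score map's calibration
belongs to the loss, not to batch statistics.

## Losses and training

Least-squares adversarial losses:

$$J(D) = \tfrac12\,\mathbb{E}\big[(D(y)-1)^2\big] + \tfrac12\,\mathbb{E}\big[D(G(x))^2\big]$$
$$J(G) = \tfrac12\,\mathbb{E}\big[(D(G(x))-1)^2\big] + \lambda\,\mathbb{E}\big[\lVert G(x)-x\rVert_2^2\big]$$

The pixel term compares the generated patch with its *own input* — not
with any target — which is what makes unpaired training possible: the
adversary supplies the domain statistics, the pixel term supplies the
anatomy. The exact norm of the pixel term is exposed as configuration
(`l2` default, `l1` selectable) and λ defaults to 10, a conventional
weight for constrained least-squares GAN translation; both are knobs
because the published description fixes neither.

Training alternates one discriminator step (real standard-dose patches
toward 1, generated patches toward 0) and one generator step per
mini-batch, with Adam at learning rate 2e-4. Betas (0.5, 0.999) follow
adversarial-training convention (the default 0.9 first moment is known to
destabilize GANs). Mini-batch 40, 200 epochs and 128-px training patches
are the clinical-scale defaults; "mini-batch of 40" we read as 40 patches.
Patches are sampled at uniformly random offsets rather than on the fixed
stride-32 grid — the grid is an inference-time device; random offsets are
its training analogue, and `patchesPerImage` recovers grid-like coverage.
An epoch is one pass over the low-dose corpus's patch budget. All weights
start from N(0, 0.01) (batch-norm scale starts at 1, shift 0); a
non-finite loss aborts with the offending epoch, the only early-stopping
mechanism provided.

## Haar convention

The published description fixes no wavelet normalization, so the package
uses the orthonormal convention — every 2-D filter tap ±1/2, so for a 2×2
block $[a\,b;\,c\,d]$: $LL=(a+b+c+d)/2$, $LH=(a-b+c-d)/2$ (detail along
width), $HL=(a+b-c-d)/2$ (detail along height), $HH=(a-b-c+d)/2$.
Orthogonality buys three testable properties: perfect reconstruction,
energy conservation, and an adjoint equal to the inverse (so the backward
pass through the wavelet operators is the opposite transform — no separate
gradient code to get wrong). Odd-sized inputs are a hard error rather than
silently padded: inside the network all sizes are even by construction,
and padding would break invertibility.

## Normalization window

Networks want bounded inputs; CT is unbounded in HU. The package maps the
abdominal soft-tissue display window (width 250, level 125), widened to
[−160, 400] HU, linearly onto [−1, 1]: $x' = (x - 120)/280$. The map and
its exact inverse are stored in every checkpoint, so inference restores HU
exactly; the identity-generator test demonstrates the whole
normalize→patch→generate→reassemble→denormalize composition is lossless to
1e−6 HU. Normalization is per-image-window (fixed), not per-patch:
per-patch statistics would erase exactly the attenuation differences the
model must learn.

## Patch pipeline

Offsets form the arithmetic grid {0, s, 2s, …} per axis; when (dim − p) is
not a multiple of s a final flush-to-edge offset at dim − p covers the
border (the clinical 512/128/32 case is exact: 13×13 = 169 patches,
interior coverage 16, corner coverage 1). Reassembly accumulates in
extended precision and divides by the exact integer coverage count, so
averaging k copies of the same value returns that value bit-exactly —
extract followed by reassemble is the bit-level identity, which the tests
assert on the full 512² grid. Windows are half-open [o, o+p), offsets
0-based, row-major.

## Phantoms: what they emulate, what they do not

The simulator renders a body ellipse containing a liver ellipse, a
portal-vein disc inside the liver, and two paraspinal-muscle discs, on an
air background fixed at −1000 HU. Region means follow the two dose
domains' measured organ values; dose noise is additive stationary Gaussian
in HU. That choice is deliberate: the metric the whole analysis rests on
(ROI standard deviation) sees only the noise magnitude, and a Gaussian
field makes every oracle analytic — the configured SD *is* the expected
SDn, which the tests recover to a few tenths of an HU over 20 seeds. The
kVp contrast effect is modeled as per-tissue mean shifts (a contrast scale
on tissue tables), not spectral physics, because only mean attenuation is
ever measured.

Per-image geometric jitter (axes/radii scaled by U(0.95, 1.05), centers
shifted by up to ±5% of the primitive's own extent) prevents the
adversary from keying on a fixed layout; rare draws violating the
containment constraints (vein ⊂ liver ⊂ body, muscles disjoint from
liver) are redrawn. The published per-patient spreads (e.g. 247.3 ± 47.2)
mix inter-patient and intra-image variability with no way to separate
them; the package puts the variability into geometry jitter and leaves
per-tissue texture SD at 0 by default (it is a `tissueSpec` field for
users who want textured parenchyma), keeping the noise oracle exact.

What passing tests on these phantoms show: the pipeline's arithmetic is
right, the adversarial mechanism moves both noise and attenuation in the
clinically observed direction, and every metric measures what it claims.
What they cannot show: performance on real anatomy (texture, vessels,
partial volume), scanner noise correlation/texture, or clinical effect
sizes. No projection-domain physics, beam hardening, or 3-D structure is
simulated.

## Quality metrics: conventions

ROIs are circles; a pixel belongs if its *center* lies inside. Standard
deviations are sample (n−1) SDs, matching scanner-console convention.
Liver attenuation is the mean of four parenchymal ROIs; muscle, of the two
sides; SDn is the mean of the two muscle ROI SDs. CNR and SNR are exact
closed forms; SDn = 0 raises an undefined-metric error rather than
returning an infinity. Note that a mean of per-image ratios differs from
the ratio of group means — comparisons should use one convention
consistently.

The NPS uses non-overlapping 32×32 tiles fully inside the homogeneous
mask (overlap would correlate the averaged periodograms); each tile is
divided by its mean and reduced by 1 (the stated intensity normalization —
no polynomial detrend), transformed, and the squared magnitudes scaled by
pixel-area/tile-pixels are averaged and radially binned at one DFT step
per bin. AUC is the trapezoidal integral of the radial curve;
peak frequency is the argmax with the DC bin excluded and ties broken
toward low frequency. By Parseval the 2-D spectral integral equals the
relative variance of the fluctuation field, which the tests verify within
5% on white noise. Frequencies are cycles/mm when pixel spacing is known,
cycles/pixel otherwise. On the 128-px desk phantoms the liver admits no
full 32-px tile, so desk-scale NPS comparisons use 16-px tiles — same
estimator, smaller support.

Dose arithmetic: ED = DLP × K; reductions are
(mean_SD − mean_LD)/mean_SD × 100, rounded to one decimal for display, and
scale-invariant by construction.

## Problem sizes and the scaled-down study

The package's own validation study is deliberately small: 20 + 20
phantoms of 128×128, a depth-2 generator with 8 base features, 30 epochs
of batches of 10 training patches of 32 px, evaluated on 5 held-out
low-dose phantoms — about 25 seconds per run on one CPU, repeated over 10
seeds in the test suite. At this scale only the *direction* of the effect
is asserted: held-out noise strictly decreases, and the portal-vein mean
moves negatively, toward the standard-dose domain. Magnitudes are not
asserted anywhere: a desk-scale model on geometric phantoms over-smooths
(SDn far below the standard-dose 11 HU) and overshoots the attenuation
shift, and clinical effect sizes require clinical data and clinical-scale
training (supported by configuration: depth 4, 64 features, batch 40, 200
epochs) that no test should attempt.

## Numerical choices, degenerate inputs

* Convolutions run through im2col/GEMM kernels (RcppArmadillo); batch
  normalization uses biased batch variance with eps 1e−5 and running
  statistics (momentum 0.1) for inference.
* Backpropagation is verified against central finite differences at
  eps 1e−6 — small enough to sit inside a leaky-ReLU linear piece; at
  larger eps the kinks bias the quotient, which is a property of the
  check, not of the gradients.
* The wavelet adjoint is the inverse transform (orthogonality), so no
  separate backward kernels exist for it.
* Empty score maps, mismatched patch shapes, ROIs touching the image
  border, regions with no full NPS tile, zero SDn, zero standard-dose
  means, odd wavelet inputs, patch sizes exceeding the image or not
  divisible by 2^depth: all are explicit errors naming the offence, never
  silent coercions.
* Checkpoints embed format version, architecture, normalization window,
  parameters, batch-norm state and seed; loading an unknown version is an
  error.

## Known limitations

Single-slice 2-D only; no DICOM series/volume semantics. The hand-written
DICOM layer covers single-frame explicit-VR little-endian CT (it is
cross-checked against an independent reader in the tests) — not the full
standard. Uniform overlap averaging only (no feathered blending). No
learning-rate schedules, no multi-GPU, no mixed precision. The phantom
noise is white; real CT noise is spatially correlated by the
reconstruction kernel, so phantom NPS curves are flat where clinical ones
peak mid-band.
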