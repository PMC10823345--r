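---
title: "Methods: large-kernel 3D segmentation of brain metastases and volumetric response assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: large-kernel 3D segmentation of brain metastases and volumetric response assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlkunet)
```

## The problem

Brain metastases (BMs), most often from lung cancer, are screened and
followed with contrast-enhanced brain MRI. Two clinical tasks dominate the
workload: finding every enhancing lesion — including metastases only a few
millimetres across — and quantifying how the total tumour burden changes
between a baseline and a follow-up scan. On 3D black-blood (BB)
T1-weighted images the intravascular signal is suppressed, so enhancing
metastases stand out against dark vessels; residual unsuppressed vessels
near the brain surface and the contrast-enhancing choroid plexus remain
the canonical false-positive sources. A further physiological subtlety is
necrosis: treated metastases develop non-enhancing dead cores that, per
the RANO-BM guidance, must be excluded both from the segmentation and from
any volumetric response measurement.

This package implements that full pipeline — a large-kernel 3D
encoder/decoder segmentation network, mask-based false-positive
suppression, lesion-level evaluation, and a volumetric three-category
response classification — together with a synthetic phantom generator that
makes every stage testable without clinical data.

## The network

The segmentation model is a 3D U-Net variant with `n_levels` (default 4)
resolution levels. Each encoder block applies

1. a pointwise (1×1×1) channel expansion,
2. two *parallel depthwise* convolutions — a large kernel (default
   13×13×13) and a small one (default 5×5×5) — each followed by
   batch normalization,
3. the sum of the two branches through a GELU activation, and
4. a pointwise projection.

Depthwise convolutions act per channel, which is what makes a 13³ kernel
affordable in 3D; the large kernel gives each level a receptive field that
spans a whole metastasis plus its context instead of accruing it slowly
through stacked 3×3×3 layers. Downsampling between levels is a learned
stride-2 depthwise convolution; the decoder mirrors the encoder with
trilinear upsampling, a pointwise mix, concatenation of the matching
encoder feature map (skip connection), and a 3×3×3 depthwise refinement.
A two-channel softmax head yields per-voxel background/foreground
probabilities.

### Structural re-parameterization

The two-branch block exists only at training time. For inference each
branch's batch normalization is folded into its kernel
(`w' = w γ/√(σ² + ε)`, `b' = β − μ γ/√(σ² + ε)`), the small kernel is
zero-padded symmetrically to the large edge, and kernels and biases are
summed into one depthwise kernel per block (`fuse_reparameterize()`,
`fuse_network()`). The fused forward is algebraically identical to the
multi-branch inference forward; the test suite verifies agreement to
below 1e-10 on random blocks, which is floating-point noise.

### Multiscale highlighting of foregrounds (MHF)

The decoder is supervised at every scale, not just at full resolution:
each coarser decoder feature map carries an auxiliary two-channel head,
and its target is the ground truth downsampled by repeated 2×2×2
*max*-pooling (`mhf_targets()`), so a small lesion remains foreground at
every scale rather than being averaged away. Auxiliary losses are
weighted geometrically (`aux_loss_decay^s`, default 0.5). The mechanism
keeps small, low-contrast lesions visible to the coarse decoder stages.
Because the original gating formulation is not fully specified in public
sources, the package exposes a second realization behind
`mhf_mode = "gating"`, which additionally multiplies each decoder feature
map by `1 + p_fg` of its scale's foreground probability; both modes are
exercised by the gradient tests, and deep supervision is the default.

### Loss, optimizer, and training regime

The loss at every supervised scale is cross-entropy plus soft Dice
(`1 − (2Σp·y + ε)/(Σp + Σy + ε)`, ε = 1e-5); the composite loss is the
full-scale term plus the decayed auxiliary terms. The optimizer is Adam
(lr 1e-3, β = 0.9/0.999), chosen as the field's default for medical
segmentation. Training is whole-volume (no patching) at the package's
desk scale: one volume per optimizer step, intensities z-scored per
volume, no dropout or augmentation, so a fixed seed makes the entire
recipe bit-reproducible. The engine — forward, hand-derived backward
pass, and Adam — is implemented in R with the depthwise convolutions,
resampling and labelling in C++; analytic gradients are validated against
central finite differences in the test suite.

Channel widths (base 16, doubling per level), the normalization type, the
optimizer schedule and the absence of patching are this package's own
choices; they are deliberately surfaced in `network_config()` rather than
hard-coded.

## False-positive suppression

Postprocessing operates solely on the foreground probability channel.
Two masks define the suppression region: a *surface shell* — the brain
mask minus its erosion by `round(thickness/spacing)` voxels per axis
(default 2 mm), where unsuppressed vessels concentrate — and a *choroid
plexus* mask (for phantoms, the generator's own; atlas registration on
real data is out of scope). An optional vessel mask joins the union when
one is available. Two modes are provided:

- `zero_probability` (default): set the foreground probability to zero
  inside the union, then threshold (default 0.5) and drop components
  smaller than `min_component_voxels` (default 2). This follows the
  foreground-channel formulation literally.
- `component_filter`: threshold first, then drop whole components whose
  in-mask voxel fraction reaches θ (default 0.5). This variant cannot
  bisect a true lesion that merely touches the shell, at the cost of a
  tunable fraction.

Both modes are monotone (never add a voxel) and idempotent, which the
property tests assert on random maps.

## Lesion-level evaluation

Connected components use 26-connectivity throughout. A ground-truth
lesion counts as detected when it overlaps the union of predicted
components by at least one voxel; each predicted component is assigned to
its maximum-overlap ground-truth lesion (ties to the lower id) and is a
false positive when it overlaps none. Counting true positives on the
ground-truth side for sensitivity and on the prediction side for
precision keeps split and merge cases well defined. The any-overlap
criterion is the package's own choice — published lesion-level metrics
rarely state theirs — and is the most conservative oracle-checkable rule.

Size stratification converts each component's solid volume to an
equivalent sphere diameter, `(6V/π)^(1/3)`, with the 10 mm boundary
inclusive to "small". Per-lesion Dice scores a missed lesion as 0 and a
lesion's prediction as the union of components assigned to it; the global
all-voxel Dice is reported alongside. Paired volumetric agreement uses
the Pearson product-moment correlation and Bland–Altman limits at
mean ± 1.96 sample standard deviations of the differences. Two empty
masks have Dice 1 by convention (reported with a message).

## Volumetric response assessment

For a baseline/follow-up pair of (co-registered) segmentations, lesions
are linked greedily by descending spatial overlap, then by centroid
distance (≤ 5 mm default) for non-overlapping pairs; unmatched follow-up
components of at least `new_lesion_min_voxels` (default 2, so single-voxel
noise cannot force progression) are new lesions. Classification uses the
total solid enhancing volume over all lesions — necrosis never enters,
because the ground-truth convention excludes it:

- **PD** (progressive disease): any new lesion, or a relative volume
  increase of at least 72.8 % (boundary inclusive). The threshold is pure
  spherical geometry: a 20 % diameter increase of a perfect sphere is a
  `1.2³ − 1 = 72.8 %` volume increase, tying the volumetric rule to the
  established unidimensional progression criterion.
- **CR** (complete response): follow-up volume exactly zero and no new
  lesion — attainable because the minimum-component filter removes
  speckle.
- **PR_SD** otherwise (partial response and stable disease merged).

A zero baseline volume raises an error instead of silently classifying.
Rater agreement over cohorts is summarized by a 3×3 confusion matrix,
percent agreement, and ICC(2,1) — the two-way random-effects,
absolute-agreement, single-rater intraclass correlation — computed from
the two-way ANOVA mean squares with the F-based 95 % confidence interval
of McGraw and Wong. Categories are coded ordinally CR = 1, PR_SD = 2,
PD = 3 for the ICC; this coding is a package decision and is stated
prominently because agreement statistics on categories depend on it.

## The phantom generator

`generate_phantom()` emulates the *geometry and contrast logic* of
contrast-enhanced black-blood T1WI at toy scale: a dark background, a
mid-grey ellipsoidal brain, bright quasi-spherical lesions (axis-aligned
ellipsoids with axis scale factors in [0.8, 1.25]), darker non-enhancing
necrotic cores (probability 0.3, core radius 0.45 of the lesion radius by
default) that the ground truth excludes, bright random-walk vessel tubes,
a bright periventricular choroid-plexus-like ellipsoid, and additive
Gaussian noise added last. Lesions are placed by rejection sampling with
a minimum two-voxel gap (restarting the whole configuration when a
placement stalls), so the number of connected components equals the
catalog length by construction and detection metrics are exactly
checkable. All randomness flows through one seeded generator per call and
the session RNG is left untouched.

Intensity levels are free parameters (defaults: background 0, brain 60,
rim 200, necrotic core 35, vessel 180, choroid 190, noise SD 4): no
public source reports the real intensity distributions, so the defaults
were fixed once to give black-blood-like contrast ordering and are not
calibrated to any cohort. What the phantom deliberately does *not* model:
MRI physics (bias fields, partial volume, k-space artifacts), deformable
lesion textures, anatomy beyond one brain-shaped ellipsoid, and
registration error between timepoints (`simulate_followup()` reuses the
baseline geometry, i.e. timepoints are perfectly co-registered). Passing
tests on phantoms therefore demonstrates the correctness of the
*machinery* — architecture, losses, metrics, rules — not clinical
performance on real MRI.

## The experiment harness

`stratified_kfold()` splits patients (never lesions) into k folds:
patients are shuffled under the seed, sorted by descending large- then
small-lesion counts, greedily assigned to the least-filled fold that
brings its stratum totals closest to their fair share, then refined by
deterministic pairwise swaps that reduce the total deviation of per-fold
small-lesion proportions from the global proportion. Fold sizes differ by
at most one; the balance property is asserted on random cohorts in the
tests. Ten percent of training patients (patient-level) are held out for
validation monitoring. `run_pipeline()` chains phantom generation,
splitting, per-fold training, prediction, suppression and pooled metrics
into one JSON report; with `response_stage = TRUE` it additionally
simulates one seeded follow-up scenario per test patient (growth,
shrinkage, disappearance, or a new lesion), classifies the response from
the ground-truth pair and from the predicted pair, and reports their
agreement. Every stage sub-seed derives deterministically from the single
run seed, so a saved `run_config()` replays to a byte-identical report.

## Numerical choices and scaled-down study sizes

Problem sizes in the tests are chosen for a desk machine and stated here
as the package's own study conditions: unit tests run on 24–40 voxel
grids; the end-to-end check trains a two-level, 8-base-channel network
with 5³/3³ kernels for 200 whole-volume Adam steps on eight 64³ phantoms
(three 6–12 mm lesions each, necrosis probability 0.25, noise SD 3) and
evaluates the four held-out phantoms after suppression, expecting lesion
sensitivity ≥ 0.7 and mean per-lesion Dice ≥ 0.5 — in our runs it reaches
sensitivity 1.0 and Dice ≈ 0.9 — and that suppression strictly reduces
false-positive components. The full-size 13³-kernel block is exercised
directly by the fusion-equivalence and receptive-field tests, which are
resolution-independent. Degenerate inputs have defined behaviour
throughout: empty masks label to zero components, a zero-variance volume
z-scores to zeros, both-empty Dice is 1, zero ground truth reports
sensitivity as missing rather than zero, and exact threshold boundaries
(0.728 relative change; 10 mm diameter) are inclusive as documented.

## Known limitations

- Phantom realism, as above; no claim transfers to clinical MRI without
  retraining and real preprocessing (skull stripping, registration, bias
  correction are out of scope).
- The choroid mask on real data would require atlas registration, which
  the package does not provide.
- Training is single-volume Adam without augmentation or patching; large
  cohorts and 13³ kernels at clinical resolution would require a GPU
  implementation.
- The ICC's ordinal coding of response categories is a convention;
  agreement numbers are not comparable across different codings.
- Leptomeningeal or dural disease and skull lesions are outside the
  model's universe.
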