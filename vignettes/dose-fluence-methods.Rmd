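---
title: "Simultaneous dose and fluence prediction: models and methods"
author: "DoseFluence authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous dose and fluence prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Inverse planning for nine-beam head-and-neck IMRT produces two tightly
coupled artifacts: a 3D dose distribution and, for each beam, a 2D fluence
map describing the modulated intensity delivered through the multi-leaf
collimator. Knowledge-based planning tries to predict both directly from a
patient's anatomy: the predicted dose serves as the objective for further
optimization, and the predicted fluence as a warm-start solution. This
package implements that joint prediction as a single convolutional network
with one shared encoder and two decoders, together with everything needed
to exercise the method end to end without clinical data: ground-truth
fluence reconstruction from MLC control points, a synthetic digital
phantom with a reference-plan optimizer, masked dual-loss training,
sliding-window inference, and a dosimetric evaluation suite.

## Data model

Every case lives on an isotropic 2.5 mm voxel grid centered on the plan
isocenter, 224 x 224 voxels per transverse slice at reference scale. The
network input has 19 channels: the PTV prescription mask (each voxel holds
the maximum prescription, in cGy, among the targets covering it), the 17
organ-at-risk masks in a fixed alphabetical order, and the CT. Targets
comprise three nested primary volumes (PTV-GTV within PTV-1 within PTV-2)
prescribed either 7000/6400/5800 or 7000/6000/5400 cGy, plus two lateral
nodal volumes prescribed one of 6000, 6200, ..., 7000 cGy. The plan uses
nine 6 MV beams at gantry angles 0, 40, ..., 320 degrees; each beam's
fluence map is 160 x 160 pixels at 2.5 mm on the isocenter plane, and the
nine maps are stacked in ascending-angle order.

Frame convention (fixed): millimetres in (left, posterior, superior) with
the isocenter at the origin; gantry angle 0 puts the source anterior and
angles increase toward the patient's left; the fluence-plane row axis is
the superior-inferior axis. With equal slice spacing and pixel pitch this
makes plane rows align one-to-one with CT slices, which is what allows a
32-slice input patch to pair with a 32-row fluence patch.

## The geometric projection head

The fluence decoder ends in a fixed linear operator rather than a learned
layer: `f = t(P) %*% v`, where `v` is a 9-channel feature volume (one
channel per beam) and `P` is the per-beam voxel-to-beamlet projection
matrix. `P[i, j]` is nonzero when the ray from the beam source through
voxel `i` hits beamlet pixel `j`, and its value is the inverse-square
factor `(SAD / source-voxel distance)^2` -- deliberately nothing else (no
attenuation or scatter). `P` is stored sparse; the forward projection and
its exact adjoint (`backprojectPlane`) are what gradient propagation uses,
so the head is differentiable by construction.

Choices the geometry leaves open and how they were fixed:

* **Splatting.** Nearest-neighbor beamlet assignment by default, with ties
  broken toward the lower pixel index, because an exhaustive per-voxel
  ray-trace oracle can then check the operator entry by entry. A bilinear
  4-pixel splat is available behind `splat = "bilinear"` for smoother
  gradients.
* **SAD** defaults to 1000 mm; the source rotates in the axial plane.
* **Patch operators** are sliced out of the full-volume operator
  (`patchOperator`), not rebuilt per patch. A sliced operator keeps the
  parent's truncation behavior: because the beam diverges, voxels outside
  the patch contribute to the patch's outermost fluence rows and are
  missing from the sliced operator, so those edge rows are systematically
  under-covered. This is exactly why the training loss trims edge rows
  (below), and tests verify that middle rows agree with the full-volume
  projection while edge rows differ.
* Nine independent per-beam sparse matrices rather than one block matrix;
  augmentation-consistency checks are then per-beam index permutations.

## Ground-truth fluence from control points

A delivered field is a sequence of control points: cumulative meterset
weight, per-leaf-pair MLC positions, jaw positions. The reconstruction
forms, for each adjacent pair of control points, the aperture at the
midpoint-interpolated positions; a plane pixel gets value 1 between the
DLG-widened leaf tips inside the jaw rectangle, the MLC transmission under
a leaf inside the jaws, and the jaw transmission outside (0 by default:
jaws opaque). The field fluence is the meterset-weight-increment-weighted
sum of these masks times the field MU. The midpoint rule (rather than
averaging the two endpoint masks) was chosen so each segment is a single
aperture evaluation; re-partitioning a static segment is then exactly
invariant. Pixel centers are point-sampled by default; a 4x4 supersampling
flag anti-aliases aperture edges when wanted. The dosimetric leaf gap
(default 1.4 mm) and transmission (default 0.015) are machine calibration
data and therefore configuration, not constants.

## The synthetic phantom and its forward engine

No clinical dataset ships with the package, so the generator provides the
statistical structure the network assumes: an elliptic soft-tissue body
with bone-like inserts and seeded CT noise; five targets (nested primaries
plus lateral nodal cylinders) and seventeen OARs as jittered parametric
shapes at plausible relative positions (cord/brainstem posterior-central,
parotids lateral and overlapping the outer target, paired organs
mirrored); prescriptions sampled from exactly the two printed triplets and
six nodal levels.

The forward dose engine is deliberately simple: per beam, beamlet fluence
times the inverse-square factor times `exp(-mu_eff * radiological depth)`,
summed over beams and finished with a 3D Gaussian blur. Radiological depth
is the path integral of relative density from a fixed two-segment HU ramp
(air -1000 -> 0, water 0 -> 1, slope 1/1500 above water). Defaults:
`mu_eff` 0.004 per mm (an effective 6 MV attenuation), blur sigma matched
to the profile resolution (3 mm at reference scale, 2 mm tiny, 1.5 mm
micro -- a fixed 3 mm blur would wash out the micro profile's small
structures), and a calibration gain of 2 cGy per MU chosen so that
clinical-range target doses are reached with per-beam fluences well inside
the 2000 MU normalization scale. The engine is linear in fluence and
exposes its exact adjoint, which the reference-plan optimizer uses:
projected-gradient descent (non-negativity projection each step) on a
weighted least-squares objective -- `(dose - prescription)^2` in the
targets, down-weighted `dose^2` penalties in OARs (weight 0.05) and the
rest of the body (0.005) -- with the step size set from a power-iteration
estimate of the objective's Lipschitz constant, which keeps the objective
monotone without line searches.

What the phantom does *not* emulate: realistic CT texture, scatter and
buildup physics, deformable anatomy, deliverability constraints on the
optimized fluence. Tests passing on phantoms therefore demonstrate that
the pipeline is mechanically and statistically sound, not that the
learned model transfers to clinical images.

## Network architecture

One encoder, five resolution levels: level 1 is two 3x3x3 stride-1
convolutions; levels 2-5 are one 3x3x3 stride-2 convolution (channels
double, every axis halves) plus one 3x3x3 stride-1 convolution. Every
3x3x3 convolution is followed by instance normalization and ReLU. At the
reference width (32 base channels) a 19 x 32 x 224 x 224 input patch
contracts to a 512-channel bottleneck of 2 x 14 x 14.

Two decoders, four levels each: trilinear x2 upsampling, concatenation
with the matching encoder feature map, then two 3x3x3 convolutions per
level -- except the finest level, which has one 3x3x3 convolution and a
linear 1x1x1 output convolution. The dose decoder ends in a 1-channel
dose patch; the fluence decoder additionally receives the dose decoder's
per-level feature maps (concatenated before the level's convolutions) and
ends in the 9-channel pre-projection volume `v`, one channel per beam,
each projected by its own patch operator into a 9 x 32 x 160 fluence
patch.

Decisions the architecture description leaves open, and what was chosen:

* The pre-projection volume has **9 channels, one per beam**; this is the
  central interpretation of how a single volumetric head can feed nine
  per-beam projections, and it is isolated behind `modelConfig()`.
* Cross-decoder connections are **concatenations** (matching the skip
  connections), taken from the dose decoder's level outputs; at the finest
  level the 3x3x3 feature map before the 1x1x1 head is used.
* Instance normalization uses **learned affine terms** (the common
  default); note a convolution bias immediately before an instance norm is
  a mathematical no-op and is kept only for uniformity.
* The two decoders share no parameters.

Implementation note: the network is hand-implemented on im2col+GEMM
convolution kernels with explicit backward passes (verified against
finite differences). Channel concatenations are never materialized --
each block convolves its input parts with slices of the weight tensor and
sums, which is algebraically identical and keeps whole-volume inference at
reference scale within a few gigabytes.

## Training

Patches are 32 consecutive slices drawn uniformly among all windows
containing at least one PTV slice. Normalizations: dose and PTV mask by
7000 cGy, fluence by 2000 MU, CT trimmed to [-1024, 2000] HU then divided
by 2000. Augmentation: left-right flip with probability 0.6 (beams remap
g to 360 - g and fluence columns reverse -- exact under the mirror
geometry) and rotation about the superior-inferior axis by one of the
eight 40-degree multiples with probability 0.4 (volumes resample
nearest-neighbor for masks, linear for CT/dose; fluence beam channels
shift cyclically), so a sample stays unaugmented with probability
0.4 x 0.6 = 0.24.

The loss is the sum of two masked mean absolute errors on normalized
scales: dose over body voxels, and fluence over the beam's-eye-view
projection of the targets dilated by 5 mm, restricted to the middle 26 of
32 patch rows (three rows trimmed per edge, the truncated-projection
edge effect above; the trim width scales with the patch at the micro
profile). Optimization: Adam, batch 2, initial rate 3e-4;
reduce-on-plateau cuts the rate by 30% when the validation loss has not
improved (relative threshold 1e-4, no cooldown) for more than 4 epochs;
150 epochs of 400 iterations at reference scale. Validation is
augmentation-free and restricted to PTV-containing slices -- the printed
model-selection rule names "high-dose-region accuracy" without a formula,
and the masked dual loss on those slices is the implementation of that
rule; the best-validation parameter set is the retained checkpoint.
Augmentation draws are per-sample (per case within a batch).

## Inference

Whole volumes are predicted with sliding windows of 32 slices at stride
24 (8 overlap slices); an overshooting final window is replaced by an
end-aligned one. Window outputs are blended per slice with a logarithmic
ramp: a slice at distance `t` from the nearer window edge (capped at the
overlap width) gets raw weight `ln(1 + t) / ln(1 + t_max)`, and weights
are normalized to sum to one across contributing windows, so constants are
reproduced exactly and non-overlapped slices are copied verbatim. The
specific logarithmic form is the package's declared interpretation of
"logarithmic smoothing of overlaps"; it is isolated behind a pluggable
profile (a linear ramp is also provided). Blending happens on normalized
values; denormalization multiplies by 7000 cGy / 2000 MU, and negative
predictions are clamped to zero with the count logged. A predicted dose
can be rescaled to match a reference plan's target coverage
(`renormalizeToCoverage`, bisection on the coverage curve within scale
bounds [0.5, 2]), mirroring the clinical re-normalization step. Since the
proprietary planning-system re-import (leaf sequencing plus final dose
calculation) is out of scope, the phantom forward engine stands in for it
when a "predicted-fluence-generated dose" is needed for three-way
comparisons.

## Evaluation

Fluence: per-beam masked MAE as a percentage of the per-beam ground-truth
maximum, evaluated inside the BEV target + 5 mm mask; SSIM (Gaussian
11 x 11 window, sigma 1.5, K1 = 0.01, K2 = 0.03, data range = ground-truth
maximum, statistics cropped by the window radius); and global gamma pass
rates at 3%/3mm with 0% and 10% low-dose thresholds. The gamma search
scans a bilinear-interpolated subgrid within 3 x DTA of each evaluated
pixel; the subgrid step is 0.1 pixel -- a 0.25-pixel step was measured to
under-pass by up to two percentage points against an exhaustive fine-grid
oracle, so the finer step is the default. Gamma is not symmetric in
(reference, evaluation); tests pin this down. Dose: cumulative DVHs and
per-structure D95% (voxel 5th percentile, lower interpolation), mean and
maximum dose, reported in Gy (the single cGy-to-Gy conversion point), for
ground-truth, predicted, and fluence-generated doses, with two paired
Wilcoxon signed-rank tests per index (exact for n <= 25 after dropping
zero differences; the normal approximation otherwise).

## Scale profiles and what the tests run

Three profiles share every physical and statistical convention and differ
only in size: `default` (224 x 224 x 64, 160 x 160 planes, 32-slice
patches, base width 32), `tiny` (96 x 96 x 32, 64 x 64 planes, base 8),
and `micro` (48 x 48 x 16, 32 x 32 planes, 16-slice patches). The test
suite trains on the micro profile -- a single CPU covers a few hundred
optimizer steps in minutes there, which is enough for the loss-halving
and single-case overfitting checks -- and runs one reference-scale
forward pass to verify the architecture constants. The single-case
overfitting check uses its own short schedule (1e-3 for 400 iterations,
then 3e-4, with the dose-term gradient up-weighted 4x because the body
mask has roughly 30x more elements than the BEV fluence mask): at this
budget a constant 3e-4 has not yet converged and a constant 1e-3
oscillates around the target accuracy. The scheduler-behavior checks
themselves pin the reduce-on-plateau arithmetic at the reference
3e-4/0.7 settings.

## Known limitations

* The phantom's forward engine is a teaching-grade model; absolute doses
  are internally consistent but not clinically meaningful.
* The projection operator ignores attenuation by design (it reproduces
  only the inverse-square effect); the fluence decoder must learn the
  rest, as in the reference architecture.
* DICOM-RT ingest is an integration point only (`ingestDicom` raises an
  informative error); no DICOM reader is bundled.
* Wilcoxon exact p-values are unavailable under tied differences; the
  implementation then uses the tie-corrected normal approximation, as
  base R does.
* At desk scale the trained networks demonstrate plumbing (loss descent,
  overfitting capacity, determinism), not clinical prediction quality.
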