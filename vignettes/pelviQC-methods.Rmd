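---
title: "pelviQC: methods and design notes"
author: "pelviQC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pelviQC: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelviQC)
```

## Why positioning quality matters

Canine hip dysplasia is scored on the ventrodorsal hip extended (VDHE)
radiograph, which assumes the pelvis lies flat and symmetric on the table.
When the pelvis rotates about the body's long axis, the two halves project
asymmetrically: the underside half is more exposed (its obturator foramen
appears wider and larger) while the topside half is foreshortened and
geometrically magnified. Because scoring landmarks shift with this
distortion, screening programs need a quantitative gate that rejects poorly
positioned films before any hip scoring happens. pelviQC implements that
gate and the statistical machinery used to validate an automated
measurement model against a human reference.

## The measurement model

Per radiograph, three left-minus-right asymmetry indices are computed:

* **AOFA** (mm²): difference in obturator foramina areas,
* **AOFW** (mm): difference in their maximum medial–lateral widths,
* **AIWW** (mm): difference in iliac wing widths (dorsal-to-ventral cortical
  landmark distance at the cranial aspect of the sacroiliac joint).

Both signed values and magnitudes are exposed (`asymmetry()` and the
`aofa()/aofw()/aiww()` accessors), because the signed left-minus-right
definition and the magnitude ("largest minus smallest") convention are both
in clinical use; grouping and thresholding consume magnitudes. When iliac
landmarks are absent, AIWW is flagged unavailable rather than reported as
zero.

Width asymmetry converts to rotation degrees through the published
regression calibrations

$$y = 1.644\,x_\mathrm{AOFW} - 0.912, \qquad
  y = 0.997\,x_\mathrm{AIWW} + 0.061 .$$

`classifyRotation()` rounds the magnitude to the nearest integer degree —
half away from zero, since the calibration source states only "rounded to
the nearest integer"; the half-even alternative is a documented option — and
maps it to minimal (0–2°), moderate (3–4°), marked (5–6°) or extreme (≥7°).
`assessQuality()` accepts a radiograph when
$|\mathrm{AOFA}| \le 50.46\ \mathrm{mm^2}$. That default threshold is the
minimal-group mean AOFA (33.28 mm²) plus the measurement model's standard
error of measurement (17.18 mm²) — `deriveThreshold()` recomputes it for any
other population — and the boundary is inclusive: the case that *defines*
the threshold should not be rejected by it. AOFW regression outputs below
zero (inputs under 0.555 mm) are reported as-is with a `belowCalibration`
flag and clamp to 0° for grouping, since a negative rotation magnitude is
meaningless: the width index simply cannot resolve rotations below about a
degree.

## The synthetic phantom

No public VDHE dataset with annotations exists, so the package carries a
phantom generator that makes every downstream stage testable with exact
ground truth. A phantom is two near-elliptical radiolucent foramina
(default semi-axes 12 × 9 mm, centers ±18 mm off the midline) surrounded by
bright cortical "bone plates", a faint midline sacral band, and two bright
iliac bars whose landmark pairs carry the iliac widths; Gaussian blur
(σ = 1 px) and additive Gaussian intensity noise (SD 0.02 on a [0, 1]
scale) make segmentation nontrivial. Two rendering profiles cover the same
89.6 mm field: `full` (448 × 448 px at 0.2 mm/px, the resolution clinical
images are resized to) and `test` (128 × 128 px at 0.7 mm/px) for fast
unit-test and training runs. The defaults were fixed once, as plausible
medium-breed geometry, before any test was written.

**Calibration inversion.** The generator's asymmetry response is defined as
the exact inverse of the rotation calibrations: at rotation θ the foramen
width difference is $\delta_w = (|\theta| + 0.912)/1.644$ mm and the iliac
width difference is $\delta_{iw} = \max(0, (|\theta| - 0.061)/0.997)$ mm,
each split symmetrically (underside widens by δ/2, topside narrows by δ/2,
keeping total area roughly constant); heights stay fixed, so truth areas
are $\pi (w/2) b$. Measuring a noiseless phantom and applying
`rotationFromAOFW()` therefore recovers θ exactly — parameter recovery is a
meaningful test, not a tautology on rendering details. At θ = 0 both
differences are defined as zero (a perfectly symmetric pelvis); the AOFW
inverse is discontinuous there because of the calibration's negative
intercept, mirroring the index's inability to resolve sub-degree rotation.
Positive θ means the animal's right side is closer to the table (the right
side is the underside); an optional `magnificationTopside` factor ≥ 1 scales
the topside foramen to emulate geometric magnification and is off (1) by
default so the calibration inversion stays exact.

**What the phantom does not emulate:** real bone texture, the femora and
patellae, breed variation in foraminal shape, craniocaudal pelvic
inclination, exposure artifacts, or annotation subjectivity. Tests passing
on phantoms therefore demonstrate the correctness of the measurement and
decision pipeline and the trainability of the network — not clinical-grade
segmentation performance on real radiographs.

`simulateRater()` adds a configurable systematic bias and Gaussian error to
true measurements, so the agreement statistics (Bland–Altman, ICC, paired t)
can be exercised against known ground truth.

## Morphometry conventions

Coordinates are 0-based `(col, row)` pixel centers; "horizontal" is the
image-column direction (the VDHE view is assumed axis-aligned — no
pelvis-axis realignment is attempted). Polygon areas use the shoelace
formula (orientation independent, self-intersection rejected);
rasterization uses scanline even-odd filling with half-open spans, so a
4 × 4 px axis-aligned square covers exactly 16 pixel centers. Mask widths
use the inclusive pixel-extent convention
`(rightmost − leftmost + 1) × spacing` with ties broken by the smallest row
index; polygon widths use the exact boundary extent. The `+1` cancels in
left–right differences, which is why width *asymmetry* from masks is
accurate to well under a pixel while each absolute width carries the usual
half-pixel quantization. Anisotropic spacing is accepted as
`(row mm, col mm)`: widths use the column spacing, areas the product. Side
labels are the *animal's* sides; the viewer-left column range maps to the
animal's right, per radiographic convention.

Because rasterized widths are quantized to whole pixels, the sub-0.25°
rotation round-trip property is verified through the phantom's exact polygon
annotations; masks are held to the coarser (one pixel-spacing) width
tolerance they can actually meet.

## Segmentation

The segmenter is a deliberately small encoder–decoder network: one
3×3-conv/ReLU encoder block, 2×2 max-pooling, a 3×3-conv/ReLU bottleneck at
double width, nearest-neighbour upsampling concatenated with the encoder
skip, a 3×3-conv/ReLU fusion block and a 1×1 output head with sigmoid. The
forward pass, analytic backpropagation and the compound loss (pixel-wise
cross-entropy plus `diceWeight` × (1 − soft Dice), default weight 1) are
implemented in C++ (RcppArmadillo); the Adam loop (learning rate 0.001,
batch size 8) runs in R. `encoderScale = "small"` (base width 8, ~3k
parameters) trains on a single CPU in minutes; `"large"` (base width 32) is
a higher-capacity variant of the same architecture for larger experiments.
Distributing pretrained clinical weights is out of scope.

Training details that were open design choices: a single foreground class
("foramen") is learned and the two sides are recovered geometrically at
prediction time (threshold 0.5, speckle components under 20 px dropped, two
largest components kept, assigned right/left by centroid column) — this is
robust to left/right confusion by construction; checkpoint selection is by
best validation Dice with early stopping (patience 5 by default); data
augmentation applies horizontal flips, rotations within ±15°, and ±20%
brightness/contrast jitter, each independently with probability 0.5, with
geometric transforms applied identically to image and mask (nearest
resampling keeps masks binary). The ±15°/±20% ranges are conventional
choices; only the transform families and the 0.5 probability are fixed by
the training recipe being emulated. Dataset splitting gives validation and
test `ceiling(fraction × n)` items and the remainder to training, which
reproduces the 248/32/32 partition of 312 items at 0.8/0.1/0.1. Everything
is deterministic under the config seed (splits, initialization, shuffling,
augmentation draws).

Prediction failures (fewer than two usable components) raise a
segmentation-failure error from `predictMasks()`; `evaluateSegmenter()`
records such images as failed with zero scores rather than crashing, so
batch evaluations degrade gracefully.

At the scale exercised by the test suite — 200 phantoms at 128 px, small
encoder, ≤ 12 epochs, a few minutes on one CPU — held-out mean Dice
exceeds 0.99 against rasterized truth; the suite asserts the conservative
bound ≥ 0.90. This demonstrates the training loop works, not that the
architecture reaches clinical performance on real radiographs.

## Statistics

All procedures accept raw data or printed summary statistics and agree
exactly when the summaries come from the raw data. The 95% confidence level
is the package-wide default, configurable per call.

* `groupSummary()`: mean ± t(0.975, n−1)·s/√n.
* `pearsonFisherCI()`: Fisher z with z ± 1.96/√(n−3); |r| = 1 degenerates to
  a point interval. `regressionR2()` is r² (simple regression).
* `leveneVarianceTest()`: one-way ANOVA on |deviations| from group means
  (median optional for the Brown–Forsythe variant).
* `welchAnova()`: variance-weighted F with Welch–Satterthwaite df₂.
* `gamesHowell()`: per-pair Welch SE and df, p from the studentized range
  distribution with k groups (`stats::ptukey`, numerically integrated by
  base R); evaluation failures are raised, never silently approximated.
* Effect sizes: `effectSizeRMS()` is |Δmean|/√((s₁²+s₂²)/2) — unweighted,
  uncorrected — because that variant reproduces published pairwise effect
  sizes computed from group summary tables; the conventional n-weighted,
  bias-corrected `hedgesG()` is provided alongside. Post hoc pairwise power
  is two-sample t power at the pair's effect size and group sizes (α =
  0.05); the power model used by the original G*Power analyses is not
  documented, so published post hoc power values are not asserted.
* `blandAltman()`: limits of agreement at mean ± 1.96 SD (1.96 literally,
  not a t quantile, following the standard definition), agreement declared
  when the t-based CI of the mean difference includes zero.
* `iccSingleAbsolute()`: the two-way, single-measure, absolute-agreement
  coefficient (MS ratio form) with the McGraw–Wong F-based CI; a consistency
  variant is included for comparison. `semFromICC()` is sd·√(1−ICC). Note
  that a published SEM of 17.18 mm² alongside SD 78.90 and ICC 0.99 is not
  reproducible from this formula (which gives 7.89); the standard formula is
  implemented and no attempt is made to reverse-engineer the discrepancy,
  which likely reflects unrounded inputs.
* Power: `anovaPower()`/`anovaRequiredN()` use the noncentral F
  (λ = n·f², equal groups, totals searched in multiples of k);
  `pairedTPower()`/`pairedTRequiredN()` the noncentral t (ncp = d·√n,
  two-sided). These reproduce the design values 180 (f = 0.25, k = 4) and
  70 (d = 0.34) exactly.

Numerical notes: printed-precision inputs limit agreement with published
interval bounds — e.g. a Fisher CI computed from r printed as 0.96 has a
lower bound of 0.9476, while the published 0.94 is consistent with the
unrounded r ≈ 0.955 — so interval comparisons in the tests are made at the
printed precision. Degenerate inputs are handled explicitly: zero-variance
paired differences give an exact decision (p = 1 at zero mean, certain
rejection otherwise), constant rating tables make the ICC undefined and are
rejected, and empty masks are errors for area/width but score Dice = IoU = 1
against another empty mask.

## I/O

DICOM reading supports uncompressed single-frame monochrome images in
implicit/explicit VR little endian; pixel spacing comes from PixelSpacing,
then ImagerPixelSpacing, and a file with neither is rejected — never
silently defaulted. MONOCHROME1 is inverted to the MONOCHROME2 convention;
per-image min–max normalization is used before segmentation (DICOM
windowing attributes are ignored). Annotations use LabelMe-style JSON
(polygons `obturator_left`/`obturator_right`, two-point line landmarks
`iliac_left`/`iliac_right`; unknown labels are preserved but ignored with a
warning, duplicate labels resolve first-wins with a warning). Phantom
images and masks are written as 8-bit PNG — lossless for the phantom's
0/255 masks and effectively lossless for its [0, 1] intensity range —
with a JSON manifest carrying the pixel spacing. Measurements travel in
mm/mm² CSV tables (comma separated, "." decimal, mandatory header); pixels
appear only at I/O boundaries.

## Test problem sizes

The suite trains the small encoder once on 200 test-profile phantoms
(≤ 12 epochs), runs a 200-replicate Monte-Carlo for the heteroscedastic
ANOVA behaviour, a 2000-pair rater simulation, and a 20000-sample
limits-of-agreement coverage check; these sizes were chosen to keep the
whole suite in the low minutes on a single CPU while leaving the asserted
properties far from their tolerance boundaries.

## Known limitations

* The phantom's intensity model is schematic; segmentation performance on
  phantoms does not transfer to clinical radiographs, and the published
  clinical Dice/IoU/ICC values are not reproducible without the original
  data and weights.
* Craniocaudal pelvic inclination, which also distorts the projection, is
  neither simulated nor corrected.
* Iliac landmarks must be supplied (annotation); there is no automatic
  landmark detector.
* The DICOM reader intentionally covers only the uncompressed monochrome
  subset used by screening archives.
* The quality decision uses asymmetry magnitude only; the direction of
  rotation is reported but plays no role in accept/reject.
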