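---
title: "Methods: contactless multi-finger vein recognition and acquisition geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless multi-finger vein recognition and acquisition geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multivein)
```

`multivein` implements the computational stack of a contactless hand-vein
acquisition platform: the first-order optics of the capture geometry, frame
synchronization of free-running sensors, stereo depth and photometric-stereo
surface normals, and a complete finger-vein recognition pipeline
(segmentation, normalization, enhancement, maximum-curvature templates,
correlation matching, protocol evaluation, SVM score fusion).  Because real
multi-finger NIR datasets are access-restricted, the package ships a seeded
synthetic generator that emulates the relevant structure of such data, so
every stage is testable against ground truth.

## Acquisition optics

The camera is a thin lens with focal length $f$, f-number $N$ and circle of
confusion $c$.  The hyperfocal distance is
$H = f^2/(Nc) + f$, and for a focus distance $s < H$ the near and far limits
of acceptable sharpness are
$D_n = s(H-f)/(H+s-2f)$ and $D_f = s(H-f)/(H-s)$, with total depth of field
$\Delta = D_f - D_n$.  For $s \ge H$ the far limit is unbounded, which
`depth_of_field()` reports through a flag rather than an error.  Angles of
view are $2\arctan(d/2f)$ per sensor dimension $d$; the diagonal uses the
active-area diagonal $\sqrt{w^2 + h^2}$, and the sensors are treated as
portrait-oriented (the short side is horizontal).  The first-order field of
view at distance $z$ is $z\,d/f$.  The f-number notation "f/2.5" is read as
$N = 2.5$; only that reading reproduces the reference working point
($H \approx 1.6$ m at $f = 4$ mm, $c = 4\,\mu$m).

```{r optics}
cam <- camera_spec(4, 2.5, 0.004, 3.7, 4.9)
depth_of_field(cam, 120)
angles_of_view(cam)
```

## Frame synchronization by claps

Free-running sensors can miss a few trigger pulses at the start of a
capture.  The capture schedule therefore brackets the payload with two
identical 10-frame binary illumination patterns ("claps") after a blank
preamble.  `detect_claps()` binarizes the per-frame mean brightness at the
midpoint of the two brightness-cluster means (a two-cluster Lloyd split, so
detection is invariant to affine brightness changes), locates both exact
occurrences of the code, and verifies that their distance equals the payload
length; any mismatch is a dropped-frame error rather than a silent shift.
The default code (`1010110011`) has no short-period self-similarity; the
exhaustive suite checks payloads 1–100 under 0–3 dropped head frames.
Brightness is averaged over the central 50% crop of each frame, which makes
the statistic robust to edge vignetting.

## Stereo depth

`rectify_pair()` implements standard two-view rectification for calibrated
pinhole cameras with 5-coefficient radial/tangential distortion: both views
are rotated so the new x-axis lies along the baseline, and each output pixel
is inverse-mapped through the rectifying rotation and the distortion model.
Depth follows the disparity law $z = Bf/d$ with $d = x_\mathrm{left} -
x_\mathrm{right} \ge 0$ and the left camera as reference.

Disparity estimation is block matching with a box-filtered
sum-of-absolute-differences cost, winner-take-all selection and parabola-fit
sub-pixel refinement.  No installed R package provides a stereo matcher, so
this step is implemented directly; it is intentionally contract-level — the
tests assert a median absolute disparity error of at most 1 px on
dot-textured scenes of known disparity, not any particular cost
aggregation.  Pixels are flagged invalid when local texture is insufficient,
when the winning cost is not clearly unique, or in the left margin
(columns up to the maximum disparity) where the full search range cannot be
evaluated.  `align_view()` forward-projects left-rectified pixels to 3-D
through a depth map and samples a second camera (e.g. the RGB view) there;
missing depth becomes counted holes.

## Photometric stereo

With at least three known unit light directions stacked in $L$, Lambertian
image formation is $I = L\,G$ per pixel, where $G = \rho\,N$ combines albedo
and unit normal.  `solve_normals()` computes the least-squares solution
$G = L^{+} I$, factoring albedo $\rho = \lVert G\rVert$ and normal
$N = G/\rho$; rank-deficient light sets are rejected by name.  Lights are
treated as infinitely distant isotropic sources; near-field falloff is
handled separately by flat-field correction (division by a constant-albedo
reference plane captured under each source), which cancels the
inverse-square irradiance field.  Shadowed pixels (intensity below 2% of the
stack's 99th percentile in any frame) and near-zero-albedo pixels are masked
instead of being fed to the solver.  With a symmetric corner rig all
reference frames share the same plane-shading constant, so flat-fielding
rescales every channel equally and leaves normals unbiased.  Frequency-domain
(Frankot–Chellappa) integration of the normal field to relative depth is
provided as an optional utility only.

## Finger segmentation and normalization

The hand is isolated by a global Otsu threshold followed by morphological
opening with a disk (radius 5 px).  Fingers are then traced iteratively:
the topmost foreground row marks the tip of the tallest remaining finger;
the trace descends row by row following the 8-connected foreground run, and
stops when the run width exceeds `width_stop_factor` (default 1.8) times the
running median width — i.e. when it reaches the palm.  The width rule is
suspended for the first `min_rows` (default 10) rows so the widening rounded
tip is not mistaken for the palm.  Each traced region is erased and the
procedure repeats up to four times; a fifth region (a thumb) is never
traced.  Fingers are found in tip-height order, so a reordering step sorts
them by mask centre-of-gravity and assigns index…little labels; with the
default palm-down presentation the right hand reads index-to-little from
left to right and the left hand the reverse (a `palm_down` flag covers the
other presentation).  Reordering requires exactly four fingers — with three
one cannot tell whether they are index/middle/ring or middle/ring/little —
so incomplete segmentations are excluded from recognition experiments.

Rotation normalization fits a least-squares line through the per-row mask
midpoints (the extremal 8% of rows are trimmed, because the rounded tip and
the possibly slanted palm cut bias them) and rotates the crop — padded so no
mask pixel can clip at the border — about the mask centroid so the axis
becomes vertical.  Midpoints are sub-pixel weighted centroids of a float
mask that is carried through the resampling, so repeated normalization is
stable; estimates below a 0.15° dead band are within quantization noise and
are skipped, making normalization idempotent.  Axes beyond 45° are rejected
as non-fingers.

## Enhancement and maximum-curvature templates

Illumination varies multiplicatively across the finger, so the baseline
enhancer divides the image by a large-kernel Gaussian estimate of the
background (homomorphic correction, mask-aware so background outside the
finger never bleeds in), then applies local contrast normalization with a
variance floor at half the global detail scale — the floor prevents
near-flat regions from being amplified into hallucinated structure.  The
enhancer is one entry in a pluggable registry; learned enhancers can be
registered by name, and none of the package's contracts depend on one.

Template extraction scans the enhanced image along four directions
(transverse, longitudinal, both diagonals; configurable down to
transverse-only).  Veins are intensity valleys, i.e. concave-up dents of the
smoothed profile where the curvature
$\kappa = P''/(1+P'^2)^{3/2}$ is positive.  Within each concave region a
score proportional to the peak curvature times the region width is deposited
at the region centre, spread over the three central profile positions to
absorb the sub-pixel uncertainty of the centre estimate.  Score planes are
summed over directions, then reinforced by aligned neighbours along each
scan direction (the weaker of the two sides supports each pixel, so isolated
peaks receive no support), and binarized at the median of the strictly
positive scores.  Numerical choices: profiles are smoothed with a Gaussian
of $\sigma = 3$ px, matched to the width of the vein valleys the generator
produces (FWHM 4–6 px) — a smaller scale tracks pixel noise and visibly
destabilizes templates; curvature below $10^{-6}$ (numerical ripple on flat
regions) is treated as zero; deposits are confined to the mask eroded by
3 px so boundary curvature never enters the template.  The input is affinely
renormalized to $[0,1]$ over the mask first, making templates exactly
invariant to gain and offset changes.

## Matching

Two binary templates are compared by cross-correlation computed in the
frequency domain, searched over translations up to 20% of the template
extent in each axis (rotation search is deliberately absent: normalization
is assumed to have removed it).  The inverse transform is rounded to integer
overlap counts, so the result is exactly the brute-force spatial search.
The peak overlap is normalized by the smaller of the two active-pixel
counts, bounding the score to $[0,1]$ with identity pairs at 1; union and
geometric-mean normalizations are selectable.  The score is symmetric in its
arguments, and the reported offset is the probe's displacement relative to
the enrolled template.

## Protocols, error rates, fusion

A protocol is one cell of the hand × camera × wavelength cross-product.
Samples without a complete four-finger segmentation are excluded; the first
remaining sample per identity is enrolled and the rest become probes, each
compared once against its genuine identity and against three distinct
zero-effort impostors drawn without replacement under a recorded seed.
FMR is the percentage of impostor comparisons at or above the decision
threshold, FNMR the percentage of genuine comparisons below it, and
HTER $= (FMR + FNMR)/2$.

The threshold is selected on the dev set (subjects sorted by id, first half)
as the smallest impostor-score grid point whose dev FMR does not exceed the
target (default 0.1%), then transferred unchanged to the eval set.  When the
target lies below the resolution of the dev impostor set every threshold
above the impostor maximum yields identical dev rates; the implementation
returns the max-margin representative — the midpoint between the largest
impostor score and the smallest genuine score above it — which is markedly
more stable under transfer at small $n$ than a value infinitesimally above
the impostor maximum.

For hand-level decisions the index/middle/ring scores of each comparison
form a 3-vector; an RBF-kernel SVM (via `e1071`, library default
hyperparameters with class-balance weights) is fit on the dev vectors, its
signed decision values are oriented so genuine scores are high, and the same
threshold rule is applied to the dev decision values.  Raw finger scores are
used by default; a z-scoring switch is provided.

## The synthetic generator

`make_identity()` derives, deterministically from a seed, per-finger
geometry and a vein network: two full-length trunks (emulating the paired
digital veins) plus 3–6 side branches, generated as biased random walks with
a smooth lateral bow and distally tapering widths, confined to the finger
silhouette.  `render_hand()` renders a bright four-finger hand with palm on
a dark background at roughly 0.3 mm/px (fingers ≈ 28–31 px wide and
115–170 px long on a 340 × 300 canvas — wide enough that the vein network,
not the silhouette, carries the identity information): veins are
Gaussian-profile intensity valleys, and each sample draws per-finger tilt
(±3°), global translation (±8 px), intensity gain (±10%), a multiplicative
linear illumination field, additive Gaussian noise (σ = 0.02) and a
per-finger vein-visibility factor in $[0.55, 1]$ emulating contact-pressure
and perfusion variation — the dominant intra-class factor in vascular
imaging, and the one that makes some single-finger comparisons genuinely
hard while rarely affecting all three fingers of a hand at once.  Identity
(the vein graph) is fixed per subject; only pose and photometry vary between
samples, which is exactly the genuine/impostor structure the evaluation
assumes.  Stereo pairs are generated by resampling a dot texture with an
affine disparity field (the image of a planar surface), and
photometric-stereo quadruples bake the same inverse-square falloff into
frames and flat-field references.

What the generator does *not* emulate: wavelength-dependent tissue optics
(850 vs 950 nm are labels on synthetic channels), specular skin reflection,
3-D pose changes beyond in-plane tilt and shift, occlusions, and the
population-level quirks of real datasets (e.g. systematically harder
left-hand data).  Passing the synthetic benchmark therefore demonstrates
the correctness and internal consistency of the pipeline, not field-grade
biometric performance.

## Benchmark scale and reproducibility

The default benchmark is 20 identities × 2 hands × 5 samples (≈ 1 minute on
one CPU), evaluated as two protocol analogs (left and right hand at one
camera/wavelength label); the full 8-way protocol grid is available through
the configuration, but the extra label combinations exercise no additional
code path on synthetic data.  Property-style tests that would need many
full benchmark repetitions (difficulty monotonicity, fusion-versus-single
stability across seeds) run at reduced problem sizes chosen to keep the
whole suite in the minutes range; the difficulty trend is asserted on the
genuine/impostor score separation, which is sensitive long before HTER moves
away from zero.  Every stochastic stage draws from an explicit seed through
`with_seed()`, so identical configurations reproduce byte-identical score
tables, and the SVM fit is deterministic.

```{r pipeline, eval = FALSE}
res <- run_pipeline(default_config(seed = 0))
res$results$RH_left_850$single$eval
res$results$RH_left_850$fused$eval
```

## Known limitations

* The stereo matcher is plain block matching with sub-pixel refinement; it
  meets the package's accuracy contract on textured synthetic scenes but is
  not a general-purpose dense-stereo method for weakly textured imagery.
* The learned vein-enhancement interface ships only with the classical
  baseline; no contract depends on a trained model.
* Matching searches translations only; out-of-plane rotation or elastic
  deformation of fingers is not modeled.
* Thresholds transferred from dev sets of a few hundred comparisons carry
  visible Monte-Carlo variance; at the default benchmark scale eval-set FMR
  can exceed the nominal 0.1% target, exactly as it does in small biometric
  studies.
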