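---
title: "Volume-based CT noise measurement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-based CT noise measurement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voinoise)
```

## The measurement model

Image noise on CT is defined as the standard deviation of the CT numbers
(HU) inside a physically homogeneous region. In chest imaging the standard
homogeneous calibration structure is the air column of the trachea, and the
conventional instrument is a 1-cm² circular region of interest (ROI) drawn
on one axial slice. An SD estimated from $n$ independent voxels has
standard error approximately $\sigma/\sqrt{2n}$, so the precision of a
noise measurement is governed almost entirely by the voxel count. A
spherical volume of interest (VOI) with the same radius,
$r = \sqrt{100\,A/\pi}$ mm for an area $A$ in cm² (5.6419 mm for
$A = 1$, giving a 0.752 cm³ sphere), multiplies the voxel count by roughly
an order of magnitude and should shrink the measurement spread by about
$1-\sqrt{n_\text{ROI}/n_\text{VOI}}$ — close to 70 % for typical 0.7 mm
reconstructions — while leaving the systematic bias essentially unchanged.
This package implements both instruments together with the reference
("true noise") pipeline needed to compare them on equal terms.

Voxel membership in both shapes uses the *centre-in* criterion: a voxel
belongs to the shape when its centre lies within the radius, with distances
measured in physical millimetres using the per-axis voxel spacing (the
z-component is the slice increment, which defines the grid geometry). This
matches how clinical ROI tools count pixels, keeps counts integer, and
makes the circle exactly the axial-slice restriction of the sphere. A
relative boundary tolerance of $10^{-9}$ mm² absorbs floating-point noise
for voxels that sit exactly on the radius. A shape that would cross the
image edge is a hard error, deliberately distinct from the
segmentation-containment exclusion described below, which is a property of
the anatomy rather than of the image grid.

## Ground truth from the segmented trachea

The reference noise level of a scan is the sample SD over a segmented
section of tracheobronchial air. Segmentation is 26-connected region
growing from a user seed among voxels below an air threshold, restricted to
a 61×61×61-voxel crop centred on the seed (shifted inward at image borders,
zero-padded when the image is smaller). The default threshold of −500 HU
sits halfway between lumen air (≈ −1000 HU) and wall tissue (≈ 0 HU), more
than ten noise SDs from either tissue at both clinical noise regimes the
phantoms emulate (21 and 33 HU medians), so the grown region is not
sensitive to its exact value. The segmentation boundary is then removed
with a single morphological erosion by the full 3×3×3 cube — the minimal
operation that strips the one-voxel shell affected by partial-volume
blending — and the SD over the eroded mask is the per-scan true noise.
Sample (n−1) SDs are used throughout; at the mask sizes involved
(≥ 10⁴ voxels) the difference from the population form is far below every
tolerance in the package.

The carina ridge is detected from axial topology alone: scanning along the
cranio-caudal axis, the ridge is the most caudal slice whose in-slice lumen
is a single 8-connected component while the next caudal slice already shows
two or more (the main bronchi). This is deterministic, anatomically faithful
for any bifurcating geometry, and invariant to in-plane translation; a
`cranial` flag handles feet-first or z-flipped volumes. Measurement heights
of 1.0, 1.5 and 2.0 cm above the ridge are converted to slices by rounding
to the nearest slice with ties going cranially (10 mm at a 0.7 mm increment
is 14.29 voxels → slice offset 14), and the isocenter is the rounded
in-plane centroid of the lumen cross-section at that slice.

## Simulated repeated measurement and exclusion

Manual placement imprecision is simulated by an exhaustive, deterministic
jitter: the isocenter is displaced by one voxel in every combination of the
three axes, giving 27 positions including the original. The jitter is
defined in voxel units, so with anisotropic spacing the 27 displacements
are anisotropic in millimetres — the literal counterpart of a reader
nudging a cursor by one pixel. No randomness enters this module.

At each position both shapes are evaluated, and if *either* contains any
voxel outside the pre-erosion segmentation, *both* are excluded at that
position. The coupling mirrors what a human reader would do (reject a
placement that visibly touches the wall, whichever tool is loaded) and
keeps the ROI and VOI samples position-paired, which the Wilcoxon test
relies on. Excluded positions stay in the output tables with
`excluded = TRUE`, so exclusion-rate accounting (27 positions × scans) is
exactly reproducible. Per scan, the height (of the three candidates) with
the fewest rejected positions is kept; ties resolve to the lowest height,
the one closest to the carina and most reliably intraluminal.

## Agreement analysis

Each method is compared to the per-scan truth with Bland–Altman analysis:
bias is the mean of measured-minus-true differences, the 95 % limits of
agreement are bias ± 1.96·SD of the differences, and *variability* is the
distance between the limits, 2·1.96·SD. All kept jitter positions are
pooled, so the 27 points of one scan share a truth value and are mutually
correlated; the limits therefore describe the spread of single measurements
around their scan's truth, not the spread of independent scans, and no
repeated-measures correction is applied to the 1.96 multiplier. This is a
deliberate choice documented here rather than hidden: it makes the
variability metric directly comparable between the two methods, which is
the only use the package puts it to.

Variability is compared with the classic mean-centered Levene test (a
one-way ANOVA F on absolute deviations from the group mean — chosen over
the Brown–Forsythe median variant because the differences are symmetric and
approximately normal by construction), and bias with the Wilcoxon
signed-rank test on position-paired differences, exact for ≤ 25 untied
pairs and normal-approximated with tie correction otherwise. Because
pooling jitter positions understates the effective sample size, a
scan-level pairing (one mean difference per scan) is available through
`run_study(pairing = "scan")`; the position-level default reproduces the
pooled analysis. Both implementations are checked against independent
references (`car::leveneTest`, `stats::wilcox.test`) to 10⁻⁸ in the test
suite, and the Levene test's empirical size at α = 0.05 is verified to sit
in [0.03, 0.07] under the null.

## What the phantom generator does and does not emulate

`phantom_spec()` describes a vertical 18 mm trachea splitting at a known
carina slice into two 12 mm bronchi diverging at 30°, walled by 3 mm of
soft tissue (0 HU) inside lung parenchyma (−870 HU), on an 81×81×96 grid at
0.7 mm isotropic spacing — the slice increment of the clinical
reconstructions the method targets. The wall is constructed as a true 3-D
dilation of the analytic lumen, so thresholded air can never leak
diagonally into parenchyma at the bifurcation. Injected noise is iid
Gaussian with known σ (default 33 HU, the ultra-low-dose regime median;
cohorts default to σ ~ U[26, 39], that regime's observed spread — use
U[17, 29] for a regular-dose arm). HU levels only need to satisfy
air/tissue contrast ≫ σ; their exact values are irrelevant to an
SD-based pipeline, which the HU-shift invariance test confirms.

The default trachea is wide enough that every jittered sphere stays inside
the lumen — a zero-exclusion geometry, appropriate for validating the
precision comparison itself. Exclusion behaviour is exercised separately
with narrowed and truncated geometries in the test suite.

The deliberate simplification is noise correlation: real CT noise is
spatially correlated by reconstruction, with vendor- and kernel-dependent
structure, while the default phantom is iid. Under iid noise the
VOI-to-ROI variability ratio follows the voxel-count law
$\sqrt{n_\text{ROI}/n_\text{VOI}} \approx 0.31$ (a ≈ 69 % reduction), and
the cohort-scale tests verify the pipeline reproduces that analytic
prediction to ±0.10. On clinical scans, correlation reduces the *effective*
voxel count of the large VOI more than that of the small ROI, so observed
reductions (40–53 %) are smaller than the iid law. The generator's
`smooth_mm` option (Gaussian-correlated noise, rescaled so the realized
field SD still equals σ) exists to explore that gap qualitatively; it does
not claim to reproduce any scanner's noise power spectrum. Passing
validation on iid phantoms therefore demonstrates correctness of the
geometry, bookkeeping and statistics — not the clinical magnitude of the
improvement, which depends on the scanner's correlation structure.

## Validation scale and numerical choices

Cohort-scale validation uses 49-scan cohorts (matching the two-arm study
design the framework is built for) and repeats the precision-ordering
check over 20 independently seeded cohorts; the ordering (sphere LoA
distance < circle LoA distance, Levene p < 0.001) must hold in all 20.
Noise-recovery checks require an eroded lumen of at least 10⁴ voxels and
tolerate 2 %, about five standard errors at that size. Geometric selectors
and the erosion are verified against brute-force triple-loop oracles on
small grids; the carina detector against constructed bifurcations,
including z-flipped and translated variants.

Other numerical decisions, gathered in one place: voxel indices are 1-based
throughout the public API (R convention, `values[i, j, k]`); centroids are
rounded with `floor(x + 0.5)` for platform-independent ties; the erosion
treats outside-the-crop as background; region growing that reaches all six
crop faces raises a leak warning rather than an error (a genuine trachea
can legitimately cross the crop in z, but never in all directions at once);
and volumes read from disk must carry positive spacing in their headers —
a missing spacing is an error, never silently defaulted, because every
millimetre-based step downstream depends on it. DICOM series input is out
of scope; convert to NIfTI or MetaImage first (`rescale_to_hu()` applies
the slope/intercept calibration if the export left it undone).

## Known limitations

- The pooled Bland–Altman limits ignore within-scan correlation of the 27
  jitter points (see above); between-method comparisons are unaffected
  because both methods share the pooling.
- The phantom is geometric, not physical: no reconstruction, beam
  hardening, cardiac motion or anatomical variability. Its role is oracle
  construction, not realism.
- Segmentation is threshold-plus-connectivity within a fixed crop; it is
  not a general airway segmenter and will under-segment severely diseased
  or stented airways. The seed point and threshold are the user's
  responsibility, as they are in the clinical workflow being modelled.
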