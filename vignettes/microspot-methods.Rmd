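---
title: "Spot detection, geometric correction and quantification of microarray images"
author: "microspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spot detection, geometric correction and quantification of microarray images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microspot)
```

# The measurement problem

A spotted protein microarray is incubated with sample, labelled with
quantum dots and photographed under UV excitation through low-cost optics.
The resulting image is geometrically unreliable: the grid appears sheared
and slightly curved, illumination varies across the field, and a high-gain
camera mode adds substantial noise. The analysis task is to report, for
each biomarker spotted in replicate, a single dimensionless value that is
comparable across chips photographed under different conditions.

The chip design makes this possible. The outer ring of the grid carries
only control spots — sheep IgG positive controls that are labelled in every
assay regardless of the sample, and ovalbumin negative controls that stay
at background level. The positive controls play three roles at once:
quality control (if they are dark, labelling failed), geometric anchors
(they are the only spots guaranteed bright, and they sit at known grid
positions), and the normalization reference.

# Pipeline

## Anchor detection

Bright pixels are segmented and grouped into 8-connected components
(diagonal neighbours of a blurred spot belong together); components smaller
than a quarter of the ROI ellipse area are discarded as noise. The default
segmentation is Otsu's threshold on the intensity histogram. A
quantile rule (probability `1 - 1.5 *` total-ROI-fraction) is also
available, but it assumes a fixed fraction of bright pixels: on a chip
whose biomarker spots carry little signal the rule descends into the
smooth background gradient and merges the brightest background region into
one giant component, which can corrupt anchor selection. Otsu adapts to
however many spots are actually lit, which is why it is the default. A
fixed threshold remains for fully controlled input.

Blob-to-grid correspondence is established corner-first: relative to the
centroid of all blob centroids, the four blobs most extreme in the four
diagonal directions are assigned to the four corner positions (all corners
are positive controls by layout invariant), preserving orientation. A
provisional affine map fitted on these four pairs projects every remaining
blob onto the reference grid, and blobs are greedily matched to the
nearest unclaimed positive-control centroid within `0.4 * min(pitch)` —
beyond that radius a blob would be closer to a neighbouring grid position
than to its own. Ambiguous corner scores (within 1 px) and duplicate
corner claims abort with a "degenerate anchor geometry" error rather than
guessing. Matching targets positive controls only; negative controls are
background-level by design and never reliably detectable.

## Two-stage geometric correction

Both fitted transforms map detected image coordinates to reference
(standardized) coordinates. The first stage is an affine map — six
coefficients, closed-form least squares — which removes shear, rotation,
scale and translation. The image is resampled directly into the
standardized window (grid bounding box plus a 0.75-pitch margin), which
realizes the crop to the spot area in the same step; a standalone
`cropToSpots()` is provided where the window itself is wanted.

Anchors are then re-detected in the corrected image. Curvature that the
affine could not express remains as a small smooth displacement field, and
matching anchors post-affine is much easier because every spot is already
within a fraction of a pitch of its reference position. The second-stage
fit is a quadratic polynomial over the monomial basis `{1, x, y, x^2, xy,
y^2}`, independently per output coordinate, requiring at least six
well-spread anchors; it nests the affine model exactly, so on shear-only
images the quadratic coefficients vanish and the second warp is a no-op.

The quadratic fit is applied on positive controls only. The canonical
layout provides 15 of them (12 on the ring plus 3 inner), well spread over
the field; up to 4 occluded ring anchors still leave a comfortable margin
over the minimum of 6.

Resampling uses the numerically inverted map: closed form for the affine,
per-pixel Newton iteration for the quadratic (seeded at the affine-part
inverse, tolerance 1e-6, at most 20 iterations; in practice the mild
curvature converges in 3–5). If more than 1% of output pixels fail to
converge the warp is rejected as non-invertible. Interpolation is bilinear
by default — `nearest` exists for exact integer-shift checks — and
out-of-bounds samples are filled with 0, the dark background of
fluorescence imaging.

## Quantification and normalization

On the standardized image every spot is measured at its reference centroid
as the median intensity over the pixels inside an ellipse (semi-axes 12 px
along columns and 9 px along rows by default, echoing the wider-than-tall
printed spot shape, and strictly smaller than half the 40 px pitch so
neighbouring ROIs cannot overlap). The median tolerates up to half the ROI
being corrupted — saturated pixels, dust, edge blur — without moving.

Replicates are aggregated as mean ± sample standard deviation (n − 1; the
error bar expresses between-spot dispersion on one chip, and a single spot
reports SD 0). Aggregation is restricted to the inner rectangle: ring
controls exist to define geometry, and their ROIs are the most exposed to
residual edge distortion, so the 3 + 3 inner controls carry the chip's POS
and NEG levels instead.

The reported value per biomarker role is
`(m_role - m_NEG) / (m_POS - m_NEG)`. One formula maps NEG to 0 and POS
to 1, is exactly invariant under gain and offset changes of the whole
image, and admits negative values when a spot reads below background —
which real chips of untreated samples do produce and which must not be
clipped. A chip whose positive-control mean does not exceed its
negative-control mean fails QC with a stage-tagged error. Replicate chips
measured on different days are combined by the arithmetic mean, reported
to three decimals with ties rounded away from zero (the convention
consistent with reference replicate panels such as
`combineRuns(c(0.004, -0.007)) == -0.002`).

# The synthetic scene generator

Real raw images for this instrument class are not publicly deposited, so
validation rests on a renderer with exact ground truth. What it emulates:

* **spots** as flat-top ellipses (contact-printed plateaus) 1.25 times the
  ROI size, smoothed with a Gaussian of sd 1.5 px — the ROI therefore
  samples the plateau, as it does on a real chip where the ROI is chosen
  inside the spot;
* **aberration** as an affine map (rotation, shear, per-axis scale,
  translation about the grid/image centres) followed by a quadratic bow in
  the image frame, parameterized by the corner displacement in px. The
  composition is an exact 12-coefficient quadratic map, so ground-truth
  centroids come from the forward formula, not from resampling;
* **background** as base level + linear gradient + corner vignette;
* **noise** as additive Gaussian (read noise under a high-gain night mode,
  default sd 3) plus a signal-proportional Gaussian approximating shot
  noise (default scale 0.05), then 8-bit quantization;
* **colour** as signal in the red channel (a long-pass emission filter
  confines the quantum-dot signal there, which is also why the default
  luminance mode is `red_only`) with a 10% green bleed.

Default aberration magnitudes are deliberately mild — shear a few degrees,
bow a few px of corner displacement — matching optics that produce
"slightly curved" grids; the construction-time validity check rejects bows
strong enough to fold the forward map (Jacobian determinant sampled over
the grid must stay positive). What the renderer does **not** emulate:
lens-model (radial/tangential) distortion, the true PSF of an aspherical
lens, LED spectra, chromatic effects, dust, or spot morphology defects
(comets, doughnuts). Passing the recovery suite therefore demonstrates
correctness of the geometry/quantification chain under the stated image
model, not robustness to every artefact a physical chip can show.

`sceneLadder()` generates seeded batches whose biomarker truth spans a
range evenly (all three biomarker roles of a chip share its truth value),
with per-chip randomized mild aberrations: rotation within 3°, shear
within 5°, scale 0.95–1.05, translation within 8 px, bow within 4 px per
axis, noise sd 3. The end-to-end recovery check runs 20 such chips —
60 truth/recovered pairs — and asks for mean absolute error at most 0.05,
Pearson r at least 0.99 and sub-pixel worst-case anchor residuals; the
observed values are about 0.009, 0.9998 and 0.26 px. Twenty chips keep the
whole suite under a minute while leaving the statistics stable across
seeds.

# Numerical and design choices

* **Coordinates**: x along columns, y along rows, origin top-left,
  y downward, pixel centres at integers, 0-based, shared by every module.
* **Grid shape**: a 48-spot chip with a controls-only outer ring and 6
  replicates per biomarker admits essentially one small rectangle, 6 × 8:
  the ring then holds 24 controls and the 4 × 6 inner rectangle holds the
  18 biomarker spots plus 6 inner controls. Strict POS/NEG alternation
  along the ring is impossible with POS at all four corners (the corner
  positions have mixed parity on the 24-cycle), so a fixed per-side
  pattern keeps the 12 + 12 split and POS corners. The whole arrangement
  is configurable through layout files; the default is one concrete,
  validated choice, not a claim about any particular physical chip.
* **Luminance** stays real-valued after the first conversion; requantizing
  to 8 bit mid-pipeline would bias medians.
* **Ties and determinism**: greedy anchor matching resolves distance ties
  by reference order then blob order; blobs are sorted by centroid; the
  analysis path contains no randomness, so re-analyzing the same image is
  bit-identical.
* **Degenerate inputs** fail loudly with stage-tagged conditions (I/O,
  config, detection, geometry, QC), which the CLI maps to distinct exit
  codes.

# Limitations

One chip per image; no watershed splitting of merged anchor spots (merged
anchors are an error, not a recovery case); no absolute concentrations —
without a protein standard the readout is normalized luminance units only;
no treated/untreated decision rule, which requires a validation study with
known false-positive and false-negative rates. Grids presented upside-down
are resolved only as far as the corner-orientation rule distinguishes the
four diagonal directions; a chip rotated by a full 90° is indistinguishable
from its transpose without asymmetric markings.
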