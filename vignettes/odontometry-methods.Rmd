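---
title: "Automated odontometry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated odontometry: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Orthodontic diagnosis leans on two families of linear measurements: the
mesio-distal width of each tooth (the "tooth size" entering Bolton's
inter-arch ratio, taken over the twelve teeth from right 1st molar to left
1st molar in each jaw) and the maxillary arch widths (inter-canine,
inter-premolar, and inter-first-molar distances between cusp tips).
Traditionally both are measured on plaster casts with calipers.
`odontometry` implements an automated pipeline that produces them from two
digital sources: CBCT-like voxel volumes and colored surface scans of
plaster models. This vignette documents the models the package implements,
the tunable parameters, the numerical choices, and the places where a
design decision had to be made; it is the authoritative description of
*why* the code does what it does.

## Coordinate conventions

A voxel volume is an `(x, y, z)` grid: x lateral, y anterior--posterior,
z axial (up). All file-facing coordinates are zero-based half-open;
internally R arrays are addressed 1-based, and a voxel with 1-based index
`i` has physical center `origin + (i - 0.5) * spacing`. All mm-valued
distances honor anisotropic spacing; voxel-space arithmetic is used only
for indexing. Hue lives on the circular unit interval `[0, 1)`, which
removes any degree-versus-fraction ambiguity in color distances.

## Jaw separation in 3D

CBCT volumes contain both arches in one grid, and the first task is a
voxel-level upper/lower split. The package follows a two-view fusion:

1. **Arch curve.** The mean intensity projection along z exposes the
   dental arch as a bright band. The projection is thresholded at its Otsu
   level, each supporting x column contributes the intensity-weighted
   centroid of its bright pixels, and a weighted quartic polynomial
   `y = q(x)` is fit through the centroids. A quartic rather than a
   parabola captures the molar flare of real arches. The fit is done
   twice: columns whose centroid is an outlier against the first fit
   (ends of the bright band truncated by the volume border bias their
   centroids) are dropped before the second. The curve is resampled to
   `n_points` (default 320) points at equal arc length and extended a few
   pixels past its support so the distal caps of the last molars still
   project onto it. Normals are unit, perpendicular to the local tangent,
   and consistently oriented buccally (away from the curve centroid).

2. **Panoramic image.** `P(c, z)` averages `2K + 1` bilinear samples of
   the volume along the normal at each curve point, `t` in `-w..w`.
   A *mean* rather than a sum keeps panoramic intensities on the input
   scale, so one enamel-level threshold serves both views. `w` defaults to
   15 voxels (about 4.5 mm at 0.3 mm spacing, half a typical crown depth);
   `K` defaults to `w` (1-voxel steps). Out-of-grid samples are excluded
   from the mean rather than padded.

3. **Slice masks and fusion.** Every slice along y is segmented into
   per-tooth masks; each mask is represented by its bounding-box center
   `(x + w/2, s, z + h/2)` (width along x, height along z -- the only
   self-consistent reading of the box convention). Teeth on the panoramic
   image are split into upper and lower sets by 2-means clustering of mask
   centroids in z, followed by a least-squares line through the midpoints
   of vertically adjacent upper/lower centroid pairs. (Which points enter
   this regression is a design decision: midpoints of adjacent pairs make
   the line pass through the occlusal gap by construction.) Each slice
   mask's representative point is projected to the panoramic frame --
   planar nearest curve point within `w`, axial coordinate unchanged --
   and its voxels are OR-ed into the upper or lower volume according to
   the panoramic mask the pixel falls in. A projected point in neither
   mask set attaches to the nearest mask within `tau = 3` panoramic
   pixels (representative points of curved molars can fall just outside
   thin masks); beyond that the slice mask is counted unassigned and
   reported, never fatal. The two binary volumes are disjoint by
   construction and the invariant is asserted.

The slice segmenter is a behavioral contract (image in, list of disjoint
binary masks out), so a learned instance segmenter can replace the
classical reference backend without code changes elsewhere. The reference
backend thresholds at the enamel level (bright-tail Otsu: Otsu applied to
the pixels above the global Otsu level, which separates enamel from bone
after background is gone), opens with a 1-pixel disc, labels connected
components, and watershed-splits oversized components on their distance
transform. Oversized means 1.5x the median component height -- and, in the
pipeline, also above an absolute single-crown cap (12 mm height, 13 mm
width). The absolute caps matter because the median-relative rule is
degenerate precisely in the cases that need splitting most: in a closed
bite *every* component is a fused upper+lower pair, and in anterior slices
the left and right incisors of each jaw fuse across the midline, so the
median itself is the fused size.

**Metal artifacts.** Streaks from dental metal exceed the enamel intensity
range by construction of the artifact; voxels brighter than
`metal_factor = 1.8` times the enamel threshold are zeroed before any
segmentation. Without this, radial streak lines merge with and displace
slice masks across the whole field of view.

**Inclination.** A known occlusal-plane inclination (the mandibular-plane
angle supplied by upstream cephalometry) is leveled out by resampling the
whole volume *before* separation: the panoramic jaw boundary is a straight
line, which can only separate level jaws -- under a 10 degree pitch the
two panoramic tooth rows become V-shaped in z and no straight line divides
them. When the angle is not supplied, the fallback estimator fits a plane
to the occlusal surface of each separated jaw (the z extreme of the teeth
voxels facing the bite plane, per (x, y) column) and takes its tilt about
x. The occlusal *surface* rather than the voxel cloud matters: crown
heights vary by tooth type, which tilts the cloud's principal plane even
in a perfectly level jaw.

## Scan segmentation: the FRNN gravity classifier

Scan points are classified teeth-vs-gum purely by color. The classifier
is fixed-radius nearest neighbors with an inverse-square "gravity"
decision statistic: candidates are all training samples within radius
`R = 0.15` (HSV units) of the query, where the distance is Euclidean over
`(dh_circ, ds, dv)` with circular hue distance
`min(|dh|, 1 - |dh|)`; the statistic is

\[ F = \sum_k \sigma(\varphi_k) / \max(d_k, \varepsilon)^2, \qquad
   \sigma(1) = -1,\ \sigma(2) = +1, \]

and `F < 0` classifies teeth, `F >= 0` -- including the empty-candidate
tie -- classifies gum. The signed mapping is a deliberate reading: a sum
of label values in {1, 2} can never be negative, so signs are the only
interpretation under which a negative-force teeth rule functions. The
floor `eps = 1e-6` guards the inverse square at exact color matches and
makes a single exact-match candidate decisive, as intended. Whether the
color metric should be HSV-Euclidean is not determined by theory; the
circular-hue Euclidean choice is flagged as such. Training colors default
to the phantom color model; for real scanners a labeled `(h, s, v, label)`
table should be supplied, since scanner color response varies and no
calibration is attempted.

The teeth-only cloud is rasterized into an axial depth map (max z per
grid cell, `depth_cell_mm = 0.25`), small planar connected clusters are
dropped as specks, and the map's validity mask records empty cells.

## Tooth identification

Per jaw, the maximum intensity projection over z gives the working 2D
image; its paired depth map stores the smallest z index attaining the
maximum, after orienting the volume occlusal-surface-first (the lower jaw
is z-flipped, recorded in the result), so "depth" always means the biting
surface. For scans the teeth depth map replaces the MIP directly and the
identical chain runs on it.

Teeth are detected by thresholding plus distance-transform watershed with
a minimum peak separation (`min_spacing_mm = 3.5`, slightly below the
narrowest mesio-distal width); each detection carries its box center.

The **jaw profile** is the outer (buccal/anterior) boundary of the closed
foreground, traced as an open curve between the two most-distal foreground
points. Arc-length smoothing splines over the boundary provide
scallop-free tangents and a dense smooth reference polyline: the raw
contour bulges around every crown, and both local tangents and
nearest-point arc projections against the raw contour are badly biased
(the bulges even fold tooth-center pixels onto the flanking notches).
The spline is fit on the central 90% of arc -- the traced boundary hooks
around the distal cap of each last molar -- and continued by straight
extrapolation along the trimmed end tangents.

The **adaptive midline** is the boundary point farthest from the boundary
centroid, restricted to the anterior (middle) third of the arc, with a
near-tie tolerance `delta_d` (default 2 pixels, about 0.6 mm): the
contiguous run of points within `delta_d` of the maximum is averaged.
Applied literally over the whole boundary, farthest-from-centroid selects
the posterior arch ends for wide, shallow arches; the anterior restriction
makes the operator well-posed while leaving the defining rule untouched
inside the window. The tolerance averages the flat anterior run without
admitting canines. The midline axis points from the midline point through
the centroid. Whether the "centre" should be the boundary centroid or the
foreground centroid is unresolved; the boundary centroid is used, and the
difference is small on phantoms.

Numbering assigns left/right by the side of the midline axis, then orders
each side's detections by the arc position of their projection onto the
boundary, nearest to the midline first, numbering 1..6 (central incisor to
1st molar). Extras beyond six are flagged unnumbered; a shortfall is
numbered as far as it goes and flagged.

The **fixed-midline baseline** -- the inferior method the adaptive
estimator replaces -- is anchored to the image frame: the central column
of the projection with an image-vertical axis. This is the reading under
which the documented failure mechanism of non-adaptive midlines operates:
any deviation between the dentition and the scanner frame (head rotation,
lateral displacement) marches teeth across a frame-fixed midline, whereas
a data-re-centered midline would be invariant to exactly those deviations.
For a dentition sitting in the anterior part of a cephalometrically
cropped volume, a 10 degree in-plane rotation about the frame center
displaces the incisors laterally by more than half a central-incisor
width, which flips sides and shifts every number on the affected side --
while the adaptive midline, being a function of the arch itself, is
unaffected.

## Landmarks and measurement

Each numbered tooth gets a ROI (detection box dilated by 3 mm) whose local
mesio-distal axis is the smooth boundary tangent at the tooth's nearest
boundary point. The **reference landmark backend** places each landmark at
the interproximal contact: the all-teeth foreground footprint is binned
along the *arch arc coordinate* (each pixel projects to the smooth curve),
and a walk outward from the tooth center stops at the first pixel-count
valley -- followed to its trough -- or at the last occupied bin of a free
end. Three numerical details earn their place:

* Watershed instance boundaries are deliberately not trusted for
  measurement. Level-by-level flooding of the distance transform places
  the boundary between two fused crowns about a millimeter inside the
  *larger* crown, not at the contact neck; the footprint pixel-count
  valley sits at the true contact.
* Binning uses linear (triangular-kernel) assignment with a light 1-2-1
  smooth: hard rounding of projections onto an oblique axis produces
  moire oscillations that masquerade as valleys.
* The walk's reach is capped by the mask span plus slack but never less
  than a plausible crown half-width (6.8 mm), so an undersized instance
  mask cannot truncate it; conversely a missing valley falls back to the
  mask extreme.

The landmark is the mean of the footprint pixels in the trough bin --
the neck pixels, i.e. the contact point. Which end is mesial follows from
the side: the boundary runs left-distal to right-distal, so increasing arc
is distal on the right side and mesial on the left.

The coarse-to-fine **cascade** wraps any per-stage predictor: stage k sees
a window of `shrink^(k-1)` (default 0.6, 3 stages) times the ROI centered
on the previous estimate and refines; estimates that exit the ROI are
clamped and flagged low-confidence. A window with marginal mask support
(< 25 px) keeps the previous estimate rather than guessing. The repo
ships the geometric reference stage (no training) and a trainable stage:
an average-pooled linear landmark regressor (16x16 pooled features,
targets normalized to the crop's unit square) fitted by hand-written
minibatch SGD with momentum, `theta <- theta - eta * (mu v + grad)`, batch
size 64, learning rate 0.001, momentum 0.95, mean-squared landmark loss.
A pooled-linear model rather than a convolutional network is a deliberate
scope choice: at desk scale it trains in seconds, is exactly reproducible,
and exercises the same loss and update rule; the cascade contract accepts
any stronger stage. The number of stages and the shrink factor have no
canonical values; 3 and 0.6 are defaults, configurable.

2D landmarks are lifted to 3D through the axial depth map (nearest valid
cell within 3 cells; all coordinates to mm) and the mesio-distal width is
the 3D Euclidean distance of the pair. For CBCT the lifting depth map is
the occlusal surface of the binary jaw mask rather than the noisy
intensity arg-max. Cusp tips are located on scan depth maps only (CBCT
crowns are too coarse at 0.3 mm): a bucco-lingual depth profile through
the landmark-pair midpoint -- for the 1st molar through the point 1/4 of
the way from the mesial landmark, targeting the mesio-buccal cusp -- is
scanned for peaks with topographic prominence above 0.5 mm; the buccal
tip is the peak on the side away from the arch centroid, and the canine
reports its single peak. Arch widths are the 3D distances between paired
left/right tips; a missing side leaves that parameter absent.

## Agreement statistics

The metrics module implements the validation statistics used for
method-agreement studies: MAE; the intraclass correlation with 95% CI
computed from the two-way mean-squares decomposition -- the two-way
random-effects, absolute-agreement, single-measure form ICC(A,1), the
standard inter-method choice, printed in every report since the form is a
choice, not a given; one-way fixed-effects ANOVA with its upper-alpha
critical value; Bland-Altman limits `mean(d) +/- 1.96 sd(d)` (sample sd);
and success-rate curves using a *strict* inequality ("deviations smaller
than" the threshold), which makes the curve 0 at threshold 0.

## The phantom: what it emulates and what it does not

Every stage is testable without clinical data through a synthetic
two-arch phantom with full ground truth. Defaults are the published
average adult dimensions: per-tooth widths 7.25, 6.74, 7.63, 7.66, 7.36,
11.03 mm (central incisor through 1st molar), 0.3 mm voxels, and a
parabolic arch (`y = 0.056 x^2`) calibrated once so the true
inter-canine / inter-premolar / inter-molar cusp distances land near the
clinical means (about 30.4, 38.5, 50.6 mm). Crowns are superellipsoids
placed tangentially along the arch: the mesio-distal exponent 4 keeps the
rendered extent analytically equal to the nominal width, the rounded
bucco-lingual profile (exponent 2) models curved crown flanks and hence
open embrasures between contacting teeth, and the z exponent 2.4 gives a
rounded occlusal. Intensities are ordered like tissue without claiming
Hounsfield fidelity: background 0, soft tissue 300, bone 900, enamel
1600, metal streaks 3000, plus additive Gaussian noise (sd 50). The
volume emulates a teeth-region crop bounded anteriorly by the incisors
and posteriorly by the jaw-joint region, so the dentition sits in the
anterior part of the frame as in cephalometrically cropped data. Stress
cases are parameters, not code paths: inter-jaw gap (0 = closed bite),
whole-scene pitch and in-plane rotation about the frame center, per-tooth
crowding displacement and rotation, missing teeth, metal streaks through
a random molar.

The scan phantom samples the occlusal surface as a point grid (0.15 mm
pitch): crown domes with Gaussian cusp bumps whose designed positions
match the CBCT truth, near-white tooth colors (low saturation, high
value) and pink gum (hue 0.97), each with seeded HSV jitter. Its ground
truth is computed by brute force over the sampled labeled points -- the
mesial/distal landmarks are the extreme points along each tooth's local
mesio-distal axis and each cusp tip is the arg-max of z over the relevant
quadrant -- so the truth width equals the landmark distance exactly and
every oracle is independent of the pipeline.

What the phantom does *not* model bounds what passing tests can claim:
no root anatomy or pulp, no beam hardening or scatter (streaks are
geometric lines, not physics), no mesh topology or scanner color
calibration, no deciduous or second/third molars, idealized symmetric
arches unless crowding is requested. Passing tests demonstrate the
algorithms' geometric and statistical correctness under controlled
conditions, not clinical accuracy.

## Problem sizes and determinism

The test suite runs module-level checks on 0.5 mm phantoms (about
132 x 168 x 88 voxels, a few seconds each) and the end-to-end checks at
the study conditions of 0.3 mm (220 x 280 x 147 voxels; an end-to-end
CBCT run takes on the order of ten seconds). Batch agreement uses 20 scan
phantoms with per-case width variation (sd 0.45 mm) so between-case
variance exists for the ICC to resolve. Everything is seeded: phantoms
are deterministic given their spec, training shuffles are seeded, and
pipeline runs on identical inputs are identical.

## Known limitations

Individual 3D tooth instance segmentation is out of scope (widths come
from 2D landmarks lifted through depth maps). The interproximal-valley
landmark assumes teeth meet at contacts; heavily overlapping crowns
(severe crowding) have no footprint neck, and measurements there degrade
to the stress-case behavior the truth records as overlap warnings. The
fixed-midline baseline is implemented for comparison only. The trainable
stage is a desk-scale regressor, not a replacement for a trained
convolutional landmark model on clinical data.
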