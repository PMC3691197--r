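---
title: "Volumetric analysis of soft-tissue swellings from photogrammetric landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric analysis of soft-tissue swellings from photogrammetric landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swellvol)
```

## The problem

Soft tissues such as the perineal swellings of female Old World monkeys are
landmark-poor: almost no point on the engorged tissue can be found again on
another individual, or on the same individual a week later. What *can* be
found reliably is a small ring of homologous anatomical points around the
structure — for anogenital swellings, six of them: the middle of the anus,
the upper end of the vaginal entrance, and the four points where the
callosities, the labia and the swelling meet. Photogrammetric reconstruction
of a handful of field photographs or video stills yields 3D coordinates for
these six **primary landmarks** plus an arbitrary number of ephemeral
**secondary landmarks** (scars, wrinkles, specks of dirt) scattered over the
tissue surface.

`swellvol` turns such a landmark cloud into a volume estimate in four steps:

1. **Orientation.** The configuration is centred on the centroid of the
   primary landmarks and rotated into the spatial principal-component frame
   of the primary landmarks only. PC1 and PC2 then span the best-fitting
   (least-squares) plane through the anatomical ring; PC3 — the z axis — is
   the direction of swelling. Secondary landmarks are carried along by this
   transform but have no influence on it. For a single configuration the
   Procrustes superimposition that a multi-specimen analysis would run first
   is degenerate (an object needs no alignment with itself), so orientation
   reduces to this centering and eigen-rotation.
2. **Scale restoration.** Photogrammetric reconstructions are defined only
   up to scale. All coordinates are multiplied by the ratio of a physically
   measured distance between two primary landmarks to the same distance in
   the reconstruction. The convention is the distance between the 3rd and
   4th primary landmarks; when no measurement exists (field video), a
   standardized 5 cm is assumed.
3. **Base plane.** Volume is measured above the horizontal plane
   `z = min(z)` through the lowest landmark of the oriented configuration.
4. **Height grid and prism sum.** Heights above the base plane are
   interpolated onto a regular grid of 60×60 *cells* (61×61 nodes) spanning
   the xy bounding box, using piecewise-cubic interpolation over the
   Delaunay triangulation of all landmark xy positions. Each cell
   contributes a rectangular prism whose height is the mean of its four
   corner-node heights; the volume is the sum of the prisms.

```{r pipeline}
g <- generate_shape("hemisphere", radius = 5, n_secondary = 2000,
                    sample_seed = 1)
estimate_volume(g$set, known_distance = g$scale_distance)
2 / 3 * pi * 5^3   # analytic volume of the r = 5 cm hemisphere
```

## Design choices in detail

### Sign conventions of the orientation frame

Eigenvectors are defined only up to sign, and nothing in the eigenproblem
prefers one direction of an axis. `swellvol` fixes the signs by rules that
refer only to the configuration itself, so that differently-posed copies of
one shape orient to bit-comparable coordinates:

* PC1 and PC2 are directed so that the first primary landmark (in
  configuration order) with a non-negligible projection projects
  *positively* onto them. An earlier draft used "largest-magnitude loading
  positive", but loadings are coordinates in the *input* basis: the rule
  changes its answer when the input is rigidly moved, and mirrored outputs
  result. The landmark-referenced rule is pose-independent because landmark
  order is anatomically meaningful and travels with the specimen.
* PC3 = PC1 × PC2, so the rotation is proper (det +1) and never reflects
  the specimen.
* If the secondary landmarks lie on average below the primary plane, PC2
  and PC3 are both negated (keeping det +1). Volume is integrated upward,
  so +z must point into the tissue bulge.

Volumes are invariant to all of these choices; only the signs of plotted x
and y coordinates depend on them. Near-degenerate primary rings (two nearly
equal in-plane eigenvalues) make the PC1/PC2 *labels* unstable between
specimens, but again not the volume, which uses only z and the xy footprint.

### The interpolant

The height surface is a piecewise-cubic interpolant over the Delaunay
triangulation of the landmark xy positions: one cubic Bézier triangle per
Delaunay triangle, with

* vertex control points equal to the landmark heights,
* edge control points `f(V_i) + ∇f(V_i)·(V_j − V_i)/3` from estimated
  vertex gradients, making the restriction to each shared edge the cubic
  Hermite determined by the two endpoints — the surface is therefore
  continuous across triangles, and
* the interior control point `b111 = 1/4·Σ(edge controls) − 1/6·Σ(vertex
  controls)`, the unique choice with quadratic precision.

Vertex gradients are estimated from the Delaunay neighbourhood (widened to
the 2-ring where the 1-ring has fewer than five members). The default
scheme fits a weighted local *plane*; a weighted quadratic fit is available
(`interpolate_heights(..., gradient = "quadratic")`) and reproduces
quadratic surfaces to rounding error. The plane fit is the default because
its gradients are bounded by the slopes actually present in the data:
quadratic fits on sparse clouds with steep rims (exactly what a 25 %
landmark subsample of a swelling looks like) occasionally produce enormous
gradients whose Bézier patches balloon far above the surface. The plane-fit
interpolant still reproduces constant and linear fields exactly, which is
what the flat-field and tilted-plane correctness tests rely on.

Triangulation uses the s-hull sweep of the `interp` package, falling back
to `deldir` for inputs with long exactly-collinear runs of points
(engineered calibration surfaces) that make the sweep give up.

### Hull limits, clamping, duplicates

* Grid nodes outside the convex hull of the landmark xy positions are
  undefined and excluded: a scattered-data interpolant has no support
  there, and extrapolating would invent tissue. Cells touching an
  undefined node contribute no volume (`outside = "zero"` instead counts
  their defined corners against zero heights; the difference is confined
  to the hull boundary ring of cells).
* Negative interpolated heights — cubic undershoot below the lowest
  landmark — are clamped to 0, since volume is defined above the base
  plane.
* Duplicate xy positions (within 10⁻⁹) are merged by averaging z, with a
  warning; a triangulation needs unique sites.
* The prism height uses the mean of the four corner nodes by default;
  `cell_sample = "centers"` samples the interpolant at cell centres
  instead. On smooth surfaces the two agree to well under a percent.

### Base-plane sensitivity

The base plane passes through the single lowest landmark, so replicate
landmarkings of one specimen can shift it and with it the absolute volume —
the dominant source of between-replicate spread in practice. The
`base_plane()` documentation and the tests exercise this deliberately: the
package reports `base_z` in every `volume_estimate` so analyses can monitor
it.

### Bootstrap subsampling

`bootstrap_volumes()` emulates variation in landmarking density: all
primary landmarks are always retained and `round(fraction/100 ×
n_secondary)` secondary landmarks (minimum 1) are drawn uniformly without
replacement, 100 replicates per fraction at fractions 25, 50, 75, 90 by
default. The fraction applies to the *secondary* count — the six homologous
points are retained separately — with `of = "total"` exposing the
alternative reading. Per-replicate RNG substreams are derived from the
analysis seed by a counter, so results are bit-reproducible and independent
of evaluation order. Replicates whose subset cannot be triangulated are
redrawn up to 10 times, then recorded as missing, and summaries report the
effective replicate count.

On the synthetic fixtures this reproduces the expected qualitative
structure: mean volume rises asymptotically toward the full-set volume as
the fraction grows (sparser clouds have smaller convex hulls and miss
surface relief), the variance of the estimates falls monotonically, and at
a fixed fraction larger specimens show larger absolute variance.

## What the synthetic shapes emulate — and what they do not

`generate_shape()` produces landmark clouds on surfaces of known volume:
hemisphere, half-ellipsoid "swelling", step pyramid (the package's stand-in
for a physical calibration object: five square levels of 30/25/20/15/10 cm
side and 1.8 cm step height, volume 4050 cm³), and a flat plate of volume
zero. Swelling-like shapes carry exactly six primary landmarks on the base
perimeter at deliberately non-uniform ring angles — a regular hexagon would
make the in-plane covariance isotropic and the PC axes numerically
arbitrary — with the 3rd–4th landmark separation returned for scale
round-trips. Secondary landmarks are placed by an area-uniform
low-discrepancy spiral with seeded jitter; the pyramid is sampled on its
plateaus with paired "guard" rings along both edges of each step riser so
that the steep cross-riser gradients stay confined to thin triangles.

These fixtures share the pipeline's *mechanisms* with real data — hull
growth, surface relief, base-plane sensitivity, scale restoration — but not
its hard parts: they have no reconstruction error correlated across views,
no landmarking-style bias between observers, and their surfaces are smooth.
Passing the oracle tests therefore demonstrates that the geometry engine is
correct, not that field estimates carry 1–5 % accuracy; published replicate
analyses of physical models show between-replicate SDs of order 7–20 % of
the mean, driven by landmarking itself.

## Numerical conditions used by the test suite

Problem sizes were chosen so the full suite exercises every claim at
meaningful resolution: oracle recovery uses 2000 secondary landmarks on the
60×60 protocol grid (hemisphere recovered within ~1.3 %, pyramid within
~1 %, both asserted at 5 %); the convergence check uses 5000 landmarks on a
200×200 grid (asserted at 2 %); rigid-pose invariance uses 20 seeded poses
at tolerance 10⁻⁶; bootstrap structure uses three half-ellipsoid fixtures
with 134/112/90 secondary landmarks — the published range of pin counts —
whose analytic volumes stand in the published 46.5 % / 29.4 % ratio
structure, at 4 fractions × 100 replicates.

## Known limitations

* Absolute volumes depend on landmarking style (number, density, placement
  of secondary points); only protocols held constant across specimens give
  comparable absolute values.
* The hull-limited grid slightly underestimates shapes whose base outline
  is convex but sparsely sampled (polygon vs. smooth outline).
* The interpolant is continuous but not C¹ across triangle edges; volume,
  an integral quantity, is insensitive to this.
* Multi-specimen Procrustes superimposition, shape-space statistics and
  closed-surface (watertight mesh) volumes are out of scope.
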