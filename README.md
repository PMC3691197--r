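# swellvol

Volumetric analysis of landmark-poor soft tissues — such as the perineal
swellings of female Old World monkeys — from 3D landmark clouds produced by
photogrammetric reconstruction of field photographs or video stills.

## The method

Soft tissues offer almost no landmarks that can be re-identified across
specimens or time. The protocol implemented here splits the landmarks in
two: a small set of homologous **primary** landmarks (for anogenital
swellings, six anatomical points around the anus, labia and callosities)
that define a reference frame, and any number of ephemeral **secondary**
landmarks (scars, wrinkles, debris) that describe the surface. Given a
landmark set `X = {x_i}` with primary subset `P`:

1. **Orientation** — centre on the primary centroid and rotate into the
   eigenvector basis of the primary covariance: `y_i = Rᵀ (x_i − mean(P))`,
   with eigenvalues in decreasing order. PC1/PC2 span the least-squares
   plane through the anatomical ring; PC3 (z) points into the swelling.
   Secondary landmarks are transformed but never influence `R`.
2. **Scale restoration** — multiply by `s = d_known / d_reconstructed`,
   where `d` is the distance between the 3rd and 4th primary landmarks
   (5 cm assumed for field video without a measured reference).
3. **Base plane** — `z₀ = min_i z_i` over all landmarks.
4. **Volume** — interpolate heights `z − z₀` onto a 60×60-cell grid over
   the xy bounding box (piecewise-cubic over the Delaunay triangulation of
   all landmark xy positions; undefined outside the convex hull; negative
   heights clamped to 0) and sum rectangular prisms:
   `V = Σ_cells Δx Δy · mean(4 corner heights)`.

The package also provides the protocol's validation arithmetic (distance
accuracy panels, replicate summaries, volume ratios and changes), bootstrap
subsampling of secondary landmarks, and synthetic landmark-cloud generators
on surfaces of known volume that make every stage testable end to end.

## Worked example

```r
library(swellvol)

# a synthetic hemispherical "swelling" of known volume: 6 primary landmarks
# on the base ring, 2000 secondary landmarks on the dome
g <- generate_shape("hemisphere", radius = 5, n_secondary = 2000,
                    sample_seed = 1)
v <- estimate_volume(g$set, known_distance = g$scale_distance)
v
#> Volume estimate 'hemisphere'
#>   volume: 258.50499 cm^3
#>   2006 landmarks, 2692/3600 cells, grid 60x60, base z = 0
g$analytic_volume        # (2/3) * pi * 5^3
#> [1] 261.7994
```

The estimate sits within 1.3 % of the analytic volume; the shortfall is the
convex-hull polygon of the sampled base ring versus the true circle.
Increasing the sampling and the grid (`n_secondary = 5000`,
`nx = ny = 200`) brings it within 0.2 %.

```r
# bootstrap the effect of landmark number on the estimate
b <- bootstrap_volumes(g$set, fractions = c(25, 50, 75, 90), n_reps = 100,
                       seed = 7, known_distance = g$scale_distance)
b$summary
#>   fraction n_effective mean_volume     variance
#> 1       25         100    257.2402 0.0302943037
#> 2       50         100    258.0941 0.0035625627
#> 3       75         100    258.3492 0.0019512511
#> 4       90         100    258.4425 0.0007757316
```

Mean volume rises asymptotically toward the full-set estimate while the
variance falls — the qualitative signature of landmark-density effects on
this estimator.

A thin command-line front end wraps the same functions:

```sh
exec/swellvol simulate --kind hemisphere --radius 5 --n 2000 --out hemi.nts
exec/swellvol volume hemi.nts --primary first6 --scale-distance 6.42788
exec/swellvol bootstrap hemi.nts --fractions 25,50,75,90 --reps 100 \
    --seed 17 --scale-distance 6.42788 --out boot/
```

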