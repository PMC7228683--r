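# ibcontour

Automatic detection of the **inferior breast-chest (IBC) contour** — the
visible crease where the lower breast meets the chest wall — and of the
**lowest visible point (LVP)** of the breast overhang, on 3D triangle-mesh
surface scans of the female torso. Both structures anchor quantitative
breast morphometry (symmetry, volume, ptosis grading) in reconstructive and
cosmetic surgery, where manual annotation on scans is slow and
operator-dependent.

## Method

The detector is purely geometric, driven by surface curvature; it needs no
texture, no nipple landmark, and no user interaction.

1. **Curvature.** Per-vertex principal curvatures (kmax ≥ kmin, in 1/mm)
   from a normal-cycle tensor estimator integrated over vertex one-rings,
   and the shape index
   S = (2/π)·atan((kmax + kmin)/(kmax − kmin)) ∈ [−1, 1]
   (+1 convex dome, 0 saddle, < 0 concave).
2. **Candidates.** sPP = { p : S < 0 and kmin < kmean }, with kmean the
   ROI-wide mean of kmin — concave vertices, minus near-flat undulation.
3. **Reference point.** Each side is binned into 5 mm blocks scored by the
   z-weighted shape-index average; block A (largest score) marks the lower
   mound, block B the highest positive block within ±15 mm laterally and
   50 mm above, and the reference point RP takes A's x and B's y.
4. **Tracing.** Candidates get angles θ about the RP (0° = straight down)
   and 5° sectors. In the sector below the RP, the point with the largest
   one-ring normal-angle within 10 mm seeds the contour; the trace then
   grows sector-by-sector in both directions, accepting the minimum-kmin
   candidate within 2L of the previous point, L = (5°π/180°)·R the sector
   arc length at RP-distance R. A natural cubic spline through the
   accepted knots is the detected contour.
5. **LVP.** Vertices of faces whose normals lie within 10° of straight
   down, laterally between the contour endpoints; the lowest such vertex.
   Absent when nothing faces down (no ptosis).

Agreement between contours (after spline resampling to 200 points each):
symmetric average nearest-point distance ave_d, and the threshold dice
coefficient Dc(t) = (#points with nearest-other-contour distance < t) /
(|A| + |B|), at t = 0.5–5 mm.

Because the clinical scans behind this method are not public, the package
ships a parametric synthetic torso generator with closed-form ground truth
(attachment crease and LVP) across ptosis grades 0–3, which the test suite
and the acceptance script run against. See the methods vignette
(`vignettes/ibc-contour-detection.Rmd`) for the model, parameter
rationale, and what synthetic validation does and does not show.

## Worked example

```r
library(ibcontour)

# a grade-2 ptosis torso: ~40k vertices, 1.5 mm mesh, 0.3 mm scan noise
case <- generate_torso(torso_params(ptosis_grade = 2, seed = 3))
det  <- detect_ibc(case$mesh)
det
#> ibc_detection: 40401 vertices, 2521 candidate points
#>   right: RP (74.0, 257.5); 49 contour points, -118.5 to 121.8 deg; LVP (79.5, 195.7, 39.2)
#>   left: RP (-72.5, 257.5); 49 contour points, -120.4 to 117.9 deg; LVP (-79.5, 196.2, 39.2)

evaluate_contours(det$sides$right$spline, case$crease$right)
#> ibc_eval: ave_d = 0.905 mm
#>   dice: 0.5 mm: 0.115, 1 mm: 0.725, 2 mm: 0.983, 3 mm: 0.988, 4 mm: 0.993, 5 mm: 0.995
```

Reading this: the reference points sit on each mound ~50 mm above the
crease; each detected contour has 49 knots spanning about ±120° of
sectors; both LVPs are present (grade 2 has an overhang) and hang ~17 mm
below the crease bottom. Against the generator's analytic crease the
detected spline is off by 0.9 mm on average, with 99% of resampled points
within 3 mm — comparable to the millimetre-scale agreement reported for
this family of methods against manual annotation. `plot(det)` draws the
anterior view with candidates, knots, spline, RPs and LVPs.

File-based workflows use the same machinery:

```sh
Rscript inst/cli/ibc.R simulate --grades 0,1,2,3 --n 2 --seed 1 --out cases/
Rscript inst/cli/ibc.R detect cases/case_g2_s001/mesh.ply --out out/
Rscript inst/cli/ibc.R evaluate out/contour_knots_right.txt \
        cases/case_g2_s001/crease_right.txt
```

`detect` writes per-side contour knots, 200-point spline samples, the LVP
and a JSON run report; runs are byte-for-byte reproducible.

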