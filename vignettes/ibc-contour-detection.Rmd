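---
title: "Curvature-based detection of the inferior breast-chest contour: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-based detection of the inferior breast-chest contour: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibcontour)
```

## The problem

In clinical stereophotogrammetry of the female torso, the inferior
breast-chest (IBC) contour is the visible crease along which the lower
breast meets the chest wall. It coincides with the inframammary fold when
there is no ptosis (breast sagging) and lies well below it when ptosis is
severe. The contour, and the lowest visible point (LVP) of the overhanging
breast, anchor downstream morphometry: symmetry, volume, and ptosis
assessment. Manual annotation on 3D scans is slow and operator-dependent;
`ibcontour` detects both structures automatically from surface curvature.

The pipeline: per-vertex principal curvatures, the shape index, a
candidate set of concave vertices, a per-breast reference point from a
weighted shape-index block grid, angular sectoring about that point,
sector-by-sector crease tracing under an arc-length chaining constraint,
cubic-spline fitting, and finally LVP detection from downward-facing
triangles.

## Coordinate convention

Scans rarely declare their axes, so the package fixes one convention and
states it everywhere: **+y is superior (up), +z is anterior (toward the
camera), +x is the viewer's right**, units are millimetres. Every
"lowest", "above" and "downward" in the code is defined against this
frame; the inferior-most point of a structure is its minimum-y point.
Meshes whose bounding-box diagonal is under 10 units are assumed to be in
metres and rescaled, with a warning. Side labels (`right`/`left`) follow
the image frame, not subject anatomy.

## Curvature estimation

`principal_curvatures()` integrates the normal-cycle curvature tensor over
each vertex one-ring:

$$T(v) = \frac{1}{A(v)} \sum_{e \ni v} \tfrac12\, \beta(e)\, \ell(e)\,
\bar e \bar e^{\mathsf T},$$

where $\beta(e)$ is the signed dihedral angle across edge $e$ (positive on
convex edges under the outward orientation), $\ell(e)$ its length, $\bar e$
its unit direction and $A(v)$ the barycentric one-ring area. The factor
$\tfrac12$ and the area normalization are fixed by a trace identity: the
trace of the summed tensor must reproduce the classical half-edge
integrated mean curvature $\int H\,dA = \tfrac12\sum_e \beta\ell$, which
pins both constants without any fitted calibration. The tensor is
projected onto the tangent plane of the one-ring vertex normal and its two
tangent eigenvalues (closed-form symmetric 2x2 eigendecomposition) are the
estimates, sorted so $k_{max} \ge k_{min}$; convex regions have positive
curvatures. One area-weighted one-ring averaging pass smooths the tensor
field, which evens out valence irregularity (icosphere-style valence-5
vertices otherwise err by ~15%; with averaging all sphere vertices are
within ~2% of $1/r$). The ring count is exposed as `smooth_rings`.

Two numerical points worth recording:

* **Direction sampling.** The tensor only sees the directions of incident
  edges. Grid meshes triangulated with alternating diagonals mix vertex
  valences 4 and 8 and bias the tensor (a saddle's curvatures come out 25%
  low); a uniform diagonal direction keeps every interior vertex at
  valence 6 and recovers the saddle exactly. The package's own mesh
  generators use uniform diagonals for this reason.
* **Mirror stability.** All per-vertex accumulations (tensor, vertex
  normals, areas) are performed in a canonical (vertex, element) order,
  and dihedral signs come from a canonical edge orientation plus a
  traversal sign. Floating-point summation order is therefore identical
  for a mesh and its x-mirror image, making curvatures — and everything
  downstream — *exactly* mirror-equivariant, not just approximately.

The shape index
$S = \tfrac{2}{\pi}\arctan\!\big((k_{max}+k_{min})/(k_{max}-k_{min})\big)$
classifies surface type on $[-1, 1]$: +1 convex dome, 0 saddle, negative
concave. When $|k_{max}-k_{min}| < 10^{-9}\,\mathrm{mm}^{-1}$ the formula
is replaced by its continuous limit $\mathrm{sign}(k_{max}+k_{min})$, and
by 0 when the sum is also below $10^{-9}$ — a flat vertex is typeless, not
an error.

Rim vertices of the cropped ROI get curvatures from their truncated
one-rings but are excluded from the candidate-threshold statistic below,
because the crop itself manufactures high curvature along the rim.

## Candidate points and the reference point

A vertex joins the candidate set when $S < 0$ and $k_{min} < k_{mean}$,
the mean of $k_{min}$ over all (non-rim) ROI vertices. The second
condition removes near-flat vertices whose shape index dips negative
through mesh undulation alone. The set intentionally keeps scattered
non-contour vertices; later geometric stages isolate the crease.

The reference point (RP) anchors all angular computations for one breast.
Each torso side is split at the midline of the x-range and binned into
5 mm x 5 mm blocks (a block holds a handful of vertices at typical scan
resolution), anchored at the side's minimum (x, y) corner. Each block
carries $aveS_i = \tfrac{1}{n_i}\sum_j S_{ij} z_{ij}$ with the weight
$z_{ij}$ the anterior protrusion above the side's minimum z, so prominent
convex regions — the breast mound — dominate. Block A is the largest
$aveS$; a window of A's column $\pm 3$ columns ($\pm 15$ mm) by 10 rows
above (50 mm, A's own row excluded — "above" would otherwise be
ambiguous) is searched and the highest positive-$aveS$ block becomes
block B. The RP takes A's centre x and B's centre y. The lateral margin
keeps the RP over the mound; the 50 mm rise keeps it above the contour
even for ptotic breasts. If nothing in the window is positive (flat or
absent mound, e.g. post-mastectomy), B falls back to A with a warning
rather than an error. All ties break row-major, bottom row first,
leftmost first — determinism is part of the contract.

## Tracing the contour

Candidates get angles about the RP,
$\theta_i = \mathrm{sign}(x_{p_i}-x_{RP})\arccos(v_1 \cdot v_2 /
|v_1||v_2|)$ with $v_1$ along $-y$, in degrees in $(-180, 180]$, and are
partitioned into 5° sectors, sector 0 centred straight below the RP. A
candidate exactly above the RP gets +180°; one coincident with the RP in
(x, y) gets 0° with a warning.

Within sector 0 the point of largest shape change, M, maximizes the
*normal angle* (NOA): the largest angle between a candidate's one-ring
vertex normal and that of any other candidate within 10 mm. The 10 mm
radius is a compromise between point-cloud sparsity (smaller radii can
find no neighbour) and drifting outside the crease region (larger radii
do). The intermediate point — the first accepted contour point — is the
candidate within 10 mm of M with minimal $k_{min}$.

Extension proceeds sector-by-sector outward in both angular directions
independently. In each next sector the accepted point minimizes $k_{min}$
among candidates within $2L$ of the previously accepted point, where
$L = (5°\pi/180°)R$ is the sector arc length at radius $R$, the in-plane
distance from the RP to the previous point ($R = 114.59$ mm gives
$L = 10$ mm). $2L$ is the largest plausible spacing between crease points
of adjacent sectors, so scattered off-crease candidates are rejected even
when their curvature is extreme. A direction terminates when its sector is
empty, when nothing passes the 2L test, or at a hard stop of $\pm 120°$:
a breast base is at most ~20 cm wide, which bounds the angular extent the
crease can subtend about the RP, and the stop guards against pathological
wrap-around on artefact-ridden candidate fields. For the first step in
each direction, $R$ uses the RP-to-intermediate-point distance. Ties on
minimal $k_{min}$ break to the smaller vertex index.

The detected knots are interpolated by a natural cubic spline per
coordinate over the cumulative chord-length parameter (the method cited
for the original algorithm names only "cubic spline"; chord length plus
natural end conditions is the standard parameter-free choice) and sampled
at 200 evenly spaced parameter values.

**Left-side processing.** The algorithm is defined once, for one side.
The left breast is processed by mirroring the mesh about x = 0 (negating
x and flipping winding — both exact in IEEE arithmetic), running the
identical algorithm, and mirroring results back. Together with the
mirror-stable curvature accumulation this makes the whole pipeline
exactly mirror-equivariant by construction, and it removes any asymmetry
the min-corner grid anchoring would otherwise introduce between sides.

## The lowest visible point

Faces whose outward normal lies within 10° of straight down ($-y$) mark
the underside of a ptotic overhang. Their vertices, filtered to lie
laterally strictly between the x-coordinates of the contour's two
endpoint knots, are LVP candidates; the minimum-y survivor is the LVP.
When no face points downward the breast has no overhang and the LVP is
reported absent — the grade-0 situation where the lowest visible contour
and the inframammary fold coincide — which is a result, not an error.

The cone axis deserves a note: descriptions of this construction
alternately reference the z-axis and "lowest y-value". Under the package's
coordinate convention gravity is $-y$, and a "lowest visible" point only
makes sense against gravity, so $-y$ is the default axis; the $+z$
reading remains available via `ibc_config(lvp_axis = "+z")` so both
interpretations can be compared on data.

## Agreement metrics

Two contours are compared after spline-resampling each to 200 points (a
detected contour from its fitted spline; a manual annotation from its raw
points). The symmetric average distance is

$$ave_d = \frac{\sum_i d(A_i) + \sum_j d(B_j)}{|A| + |B|},$$

with $d(A_i)$ the distance from $A_i$ to the nearest point of $B$; the
analogous definition for $d(B_j)$ uses the nearest point of $A$ (the
symmetric reading). The dice coefficient at threshold $t$ is the fraction
of points of both sets whose nearest-other-contour distance is strictly
below $t$; it is non-decreasing in $t$, and the default thresholds are
0.5, 1, 2, 3, 4, 5 mm. Distances use explicit coordinate differences
rather than the norm-expansion trick so that $ave_d(A, A)$ is exactly
zero.

## The synthetic test bed

The clinical scans this method targets are not publicly available, so the
package carries a parametric torso generator whose ground truth is known
analytically — validation runs against geometry the tests own, not
against fixtures that would need re-annotating.

The surface is a heightfield with a vertical shear. A gently convex chest
sheet (parabolic cylinder, radius 250 mm) carries two breast mounds:
paraboloid caps of protrusion 55 mm on disks of radius 65 mm. The cap
profile $1-u^2$ has a slope discontinuity at the rim, so the attachment
ring is a true dihedral fold — as the inframammary fold is — and the
ground-truth crease is the exact circle $\rho = r_b$ on the base sheet.
Ptosis is a downward in-plane shear $\sigma = \kappa\, r_b (1-u^2)^2$
whose envelope vanishes (value and slope) at the ring: the mound mass
sags while the crease and its fold dihedral stay put, so one analytic
crease serves all grades. Grades 0-3 map to $\kappa = 0.20, 1.00, 1.15,
1.30$: from 1.00 the shear folds the surface over, producing
downward-facing triangles, and the lowest point of the overhang — the
analytic LVP — drops strictly below the ring. That point solves
$1 + \kappa\,B'(u) = 0$ on the bottom ray (solved to $10^{-12}$ by 1-D
root bracketing on the closed-form derivative); its y is monotone
non-increasing in grade.

Two design points came out of validating the generator against its own
stated invariants. First, *any* smooth compact mound of this height and
radius has a steep shoulder that is radially concave all the way around,
so with a smooth (C1 or C2) profile the candidate set circles the mound
and tracing overruns the inferior arc — moving the concavity elsewhere
(angular blending toward a "smooth" upper profile) only relocates it.
The dihedral-fold profile concentrates the crease signature at the ring,
where it also dominates the smooth pocket concavity the shear creates
just inside the ring (with a C1 bump profile the detected valley sits
~3 mm inside the ring at grade 2-3). Second, the mound centres sit high
(y = 278 of a 300 mm ROI) so the ROI's upper boundary crops the
attachment ring at centre angles of about $\pm 110°$: only the inferior
arc — the clinically annotated portion — lies inside the ROI, and the
trace terminates at the crop boundary exactly as it does at missing data
on real cropped scans. The ground-truth arc spans $\pm 105°$.

Scan noise is a smooth band-limited Gaussian random field (64 random
cosine features, correlation length 20 mm), applied along vertex normals
with RMS amplitude 0.3 mm by default. Independent per-vertex jitter of
that amplitude would be wrong twice over: stereophotogrammetry error is
spatially correlated, and white noise of 0.3 mm at 1.5 mm vertex spacing
carries second-difference curvature noise of ~0.5 mm$^{-1}$ — several
times the crease signal — which no curvature-based method (this one
included) could survive. The correlated field perturbs curvature by
roughly $a(2\pi/\lambda)^2 \approx 0.03$ mm$^{-1}$, a realistic nuisance
level. Ground truth is always computed from the continuous surface; noise
perturbs only the mesh.

What the generator does **not** emulate: nipples (the method is
deliberately nipple-free), skin texture, left-right asymmetry, scanner
holes beyond an optional cut disk, and real crease variability — the fold
dihedral is uniform along the arc. Passing the synthetic suite therefore
shows the pipeline recovers a known crease under controlled resolution
and noise; it does not certify clinical accuracy, whose published
reference numbers come from a non-public dataset.

Default problem sizes: the recovery checks run grades 0-3 at five seeds
each with 1.5 mm mesh edge (about 40k vertices per case) and 0.3 mm
noise; unit tests use 3 mm meshes of the same geometry. On one CPU the
full sweep takes about a minute.

## Numerical choices and determinism

* Ties anywhere (block A/B, point M, sector minima, lowest-y) break to
  the smaller index / bottom-left block: detection contains no
  randomness, and two runs on the same mesh produce byte-identical
  output files.
* The synthetic generator's only randomness (the noise field) is driven
  by an explicit seed through a save/restore of the caller's RNG state.
* Degenerate meshes fail early with specific messages: zero-area faces
  are dropped, non-triangular files are format errors naming the face,
  empty candidate sets abort with "no concave candidates", and interior
  holes in the lower half of either side's bounding box abort with
  "hole in contour region" (the crease cannot be traced across missing
  surface; holes elsewhere only warn by their presence in
  `detect_holes()` output).
* A detection can fail on one side and succeed on the other; per-side
  status is recorded and only a double failure raises.

## Known limitations

* The curvature estimator is single-scale; very coarse meshes (edge
  length approaching the crease width) blur the fold below the candidate
  threshold.
* The between-endpoints LVP filter is an x-interval test, which assumes
  the contour endpoints bracket the overhang laterally; an extremely
  asymmetric contour could clip the true LVP.
* The block grid inherits the 5 mm quantization: the RP is only ever
  accurate to half a block, which is fine for sectoring but makes RP
  coordinates unsuitable as landmarks in themselves.
* On real scans with large flat regions the $k_{min} < k_{mean}$
  threshold adapts to whatever concavity exists; a torso with no crease
  at all (e.g. bilateral mastectomy without reconstruction) yields
  scattered candidates and the sector-0/NOA stage is the intended point
  of failure, reported as "no intermediate sector candidates".
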