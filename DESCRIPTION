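Package: ibcontour
Title: Curvature-Based Detection of the Inferior Breast-Chest Contour in 3D Torso Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the inferior breast-chest (IBC) contour and the lowest
    visible point (LVP) on triangle-mesh surface scans of the female torso.
    Per-vertex principal curvatures are estimated with a normal-cycle tensor
    estimator, the shape index classifies concave crease candidates, a
    weighted-shape-index block grid anchors a per-breast reference point, and
    the contour is traced sector-by-sector under an arc-length chaining
    constraint before cubic-spline fitting. Includes contour-agreement metrics
    (symmetric average distance and threshold dice coefficient), PLY/OBJ mesh
    input/output, and a parametric synthetic torso generator with analytic
    crease and LVP ground truth across ptosis grades for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
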