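test_that("PLY and OBJ round-trips preserve geometry and topology", {
  tet <- tetra_mesh()
  ply <- withr::local_tempfile(fileext = ".ply")
  write_mesh(tet, ply)
  back <- load_mesh(ply)
  expect_equal(nrow(back$vertices), 4L)
  expect_equal(nrow(back$faces), 4L)
  expect_equal(back$vertices, tet$vertices, tolerance = 1e-6)

  obj <- withr::local_tempfile(fileext = ".obj")
  write_mesh(tet, obj)
  back2 <- load_mesh(obj)
  expect_equal(back2$vertices, tet$vertices, tolerance = 1e-6)

  # synthetic torso round-trip to write precision
  ca <- quick_case(noise = 0)
  p2 <- withr::local_tempfile(fileext = ".ply")
  write_mesh(ca$mesh, p2)
  rt <- load_mesh(p2)
  expect_equal(rt$vertices, ca$mesh$vertices, tolerance = 1e-5)
  expect_equal(nrow(rt$faces), nrow(ca$mesh$faces))
})

test_that("non-triangular and broken inputs are rejected with clear errors", {
  qf <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), qf)
  expect_error(load_mesh(qf), "non-triangular face.*face 1")
  expect_error(load_mesh("does/not/exist.ply"), "cannot read")
  ef <- withr::local_tempfile(fileext = ".obj")
  writeLines("# empty", ef)
  expect_error(load_mesh(ef), "empty mesh")
  expect_error(ibc_mesh(matrix(c(0, 0, NaN), 1), matrix(c(1L, 1L, 1L), 1)),
               "empty|non-finite")
})

test_that("winding is reoriented so anterior normals point outward", {
  ca <- quick_case(noise = 0)
  f <- ca$mesh$faces
  set.seed(7)
  flip <- sample(nrow(f), nrow(f) %/% 3)
  f[flip, ] <- f[flip, c(1L, 3L, 2L)]
  fixed <- ibc_mesh(ca$mesh$vertices, f, validate = TRUE)
  fn <- face_normals(fixed)
  cz <- (fixed$vertices[fixed$faces[, 1L], 3L] +
           fixed$vertices[fixed$faces[, 2L], 3L] +
           fixed$vertices[fixed$faces[, 3L], 3L]) / 3
  ant <- cz >= mean(range(fixed$vertices[, 3L]))
  expect_gt(mean(fn[ant, 3L]), 0)
})

test_that("crop_roi behaves as an axis-aligned box filter", {
  ca <- quick_case(noise = 0)
  v <- ca$mesh$vertices
  bb <- apply(v, 2L, range)
  full <- crop_roi(ca$mesh, c(bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2],
                              bb[1, 3], bb[2, 3]))
  expect_equal(nrow(full$vertices), nrow(v))
  expect_equal(nrow(full$faces), nrow(ca$mesh$faces))

  ymid <- mean(range(v[, 2L]))
  upper <- crop_roi(ca$mesh, c(bb[1, 1], bb[2, 1], ymid, bb[2, 2],
                               bb[1, 3], bb[2, 3]))
  expect_lt(nrow(upper$vertices), nrow(v))
  # brute-force point-in-box oracle
  expect_true(all(upper$vertices[, 2L] >= ymid))
  expect_true(max(upper$faces) <= nrow(upper$vertices))

  expect_error(crop_roi(ca$mesh, c(1e4, 1e5, 0, 1, 0, 1)),
               "does not intersect")
  expect_error(crop_roi(ca$mesh, c(5, -5, 0, 1, 0, 1)), "min < max")
})

test_that("boundary loops match the single-incident-face edge oracle", {
  expect_length(detect_holes(tetra_mesh()), 0L)

  disk <- generate_analytic_surface("plane", size = 20, edge = 2)
  loops <- detect_holes(disk)
  expect_length(loops, 1L)
  expect_true(loops[[1L]]$is_rim)

  ca <- generate_torso(quick_params(noise = 0,
                                    hole = list(center = c(80, 120), radius = 8)))
  hl <- detect_holes(ca$mesh)
  expect_length(hl, 2L)
  expect_equal(sum(vapply(hl, `[[`, TRUE, "is_rim")), 1L)
  hole <- hl[[which(!vapply(hl, `[[`, TRUE, "is_rim"))]]
  expect_equal(hole$centroid[1:2], c(80, 120), tolerance = 0.1 * 8)
  # oracle: every boundary edge is used exactly once across all loops
  be <- nrow(ibcontour:::boundary_edges(ca$mesh))
  expect_equal(sum(vapply(hl, function(l) length(l$vertices), 0L)), be)
})

test_that("contour annotation files round-trip and validate", {
  pts <- contour_points(cbind(1:5, (1:5)^2, 0), label = "manual")
  f <- withr::local_tempfile(fileext = ".txt")
  write_contour(pts, f)
  back <- read_contour(f)
  expect_equal(unclass(back)[, ], unclass(pts)[, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  writeLines(c("# comment", "0 0 0", "1 0 0", "2 0 0"), f)
  expect_error(read_contour(f), "contour too short")
  expect_error(contour_points(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                                    c(2, 0, 0))), "distinct")
})

test_that("metre-scale meshes are rescaled to millimetres with a warning", {
  tet <- tetra_mesh(scale = 20)
  expect_warning(small <- ibc_mesh(tet$vertices / 1000, tet$faces),
                 "metres")
  expect_equal(small$vertices, tet$vertices, tolerance = 1e-12)
})
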