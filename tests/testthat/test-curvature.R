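# Analytic-surface oracles for the curvature estimator. Unit tests use
# slightly coarser meshes than the acceptance suite for speed; tolerances
# are the same.

test_that("principal curvatures match analytic values on a sphere", {
  sph <- generate_analytic_surface("sphere", size = 50, edge = 2)
  expect_gte(nrow(sph$vertices), 2000L)
  fc <- principal_curvatures(sph)
  expect_true(all(abs(fc$kmax - 0.02) / 0.02 < 0.10))
  expect_true(all(abs(fc$kmin - 0.02) / 0.02 < 0.10))
  expect_true(all(fc$kmax >= fc$kmin))
  expect_true(all(abs(fc$S - 1) < 0.1))
  expect_equal(sqrt(rowSums(fc$normals^2)), rep(1, nrow(sph$vertices)))
})

test_that("cylinder and plane curvatures are recovered", {
  cyl <- generate_analytic_surface("cylinder", size = 40, edge = 2)
  fc <- principal_curvatures(cyl)
  away <- !fc$boundary & abs(cyl$vertices[, 2L]) < 40
  expect_true(all(abs(fc$kmax[away] - 0.025) / 0.025 < 0.10))
  expect_true(all(abs(fc$kmin[away]) < 0.003))
  expect_true(all(abs(fc$S[away] - 0.5) < 0.05))

  pl <- generate_analytic_surface("plane", size = 30, edge = 2)
  fp <- principal_curvatures(pl)
  interior <- !fp$boundary
  expect_true(all(abs(fp$kmax[interior]) < 1e-9))
  expect_true(all(abs(fp$kmin[interior]) < 1e-9))
  expect_true(all(fp$S[interior] == 0))
})

test_that("a saddle has opposite principal curvatures and zero shape index", {
  sad <- generate_analytic_surface("saddle", size = 30, edge = 1.5)
  fs <- principal_curvatures(sad)
  ctr <- which(sad$vertices[, 1L] == 0 & sad$vertices[, 2L] == 0)
  expect_equal(fs$kmax[ctr], 1 / 60, tolerance = 0.05)
  expect_equal(fs$kmin[ctr], -1 / 60, tolerance = 0.05)
  expect_lt(abs(fs$S[ctr]), 0.05)
})

test_that("curvatures are scale covariant and the shape index scale free", {
  a <- principal_curvatures(generate_analytic_surface("sphere", 50, 2.5))
  b <- principal_curvatures(generate_analytic_surface("sphere", 100, 5))
  expect_equal(mean(b$kmax) / mean(a$kmax), 0.5, tolerance = 0.10)
  expect_true(all(abs(b$S - 1) < 0.1) && all(abs(a$S - 1) < 0.1))
})

test_that("shape index is invariant to rigid motions", {
  sad <- generate_analytic_surface("saddle", size = 30, edge = 2)
  f1 <- principal_curvatures(sad)
  set.seed(42)
  A <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(A) < 0) A[, 1L] <- -A[, 1L]
  m2 <- sad
  m2$vertices <- sad$vertices %*% t(A) +
    rep(c(5, -3, 7), each = nrow(sad$vertices))
  f2 <- principal_curvatures(m2)
  expect_lt(max(abs(f1$S - f2$S)), 1e-6)
})

test_that("the shape index formula and its degenerate limits are exact", {
  fake <- list(kmax = c(0.02, 0.025, 0.01, 0.02, 0),
               kmin = c(0.02, 0, -0.01, 0.02 - 1e-12, -1e-12))
  S <- shape_index(fake)$S
  expect_equal(S[1L], 1)                      # umbilic convex limit
  expect_equal(S[2L], 0.5)                    # (2/pi) atan(1)
  expect_equal(S[3L], 0)                      # perfect saddle
  expect_equal(S[4L], 1)                      # degenerate difference -> sign
  expect_equal(S[5L], 0)                      # fully degenerate -> 0
  expect_error(shape_index(list(kmax = NULL, kmin = NULL)), "not populated")
})

test_that("one-ring vertex normals follow the surface orientation", {
  pl <- generate_analytic_surface("plane", size = 20, edge = 2)
  vn <- vertex_normals(pl)
  expect_equal(vn, matrix(rep(c(0, 0, 1), each = nrow(vn)), ncol = 3L))

  sph <- generate_analytic_surface("sphere", size = 50, edge = 3)
  vns <- vertex_normals(sph)
  radial <- sph$vertices / 50
  ang <- acos(pmin(1, rowSums(vns * radial))) * 180 / pi
  expect_lt(max(ang), 2)

  # apex of a symmetric cone points along the axis
  n <- 12L
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  v <- rbind(c(0, 0, 10), cbind(10 * cos(th), 10 * sin(th), 0))
  f <- cbind(1L, 1L + seq_len(n), 1L + c(seq_len(n)[-1L], 1L))
  cone <- ibc_mesh(v, f[, c(1L, 3L, 2L)], validate = FALSE)
  vnc <- vertex_normals(cone)
  expect_equal(abs(vnc[1L, 3L]), 1, tolerance = 1e-12)
})

test_that("sign convention separates crease from mound on the torso", {
  ca <- quick_case(grade = 2, seed = 3)
  fld <- principal_curvatures(ca$mesh)
  v <- ca$mesh$vertices
  gt <- rbind(ca$crease$right, ca$crease$left)
  d <- brute_nn_dist(v, gt)
  expect_true(all(fld$kmin[d <= 1] < 0))
  apex <- which.max(v[, 3L])
  expect_gt(fld$kmin[apex], 0)
})

test_that("tiny and degenerate inputs are rejected or flagged", {
  expect_error(principal_curvatures(
    ibc_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
             rbind(c(1L, 2L, 3L)), validate = FALSE)), "fewer than 4")
  tet <- tetra_mesh()
  lone <- tet
  lone$vertices <- rbind(lone$vertices, c(99, 99, 99))
  expect_warning(fc <- principal_curvatures(lone), "isolated")
  expect_equal(fc$kmax[5L], 0)
})
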