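test_that("angles about the reference point follow the signed-acos formula", {
  rp <- list(x = 0, y = 0)
  v <- rbind(c(0, -10, 0),    # directly below -> 0
             c(10, 0, 0),     # same y, +x -> +90
             c(0, 10, 0),     # directly above -> +180 by convention
             c(-5, -10, 0),   # brute-force formula check
             c(-10, 0, 0))    # same y, -x -> -90
  sec <- compute_angles(1:5, rp, v)
  th <- sec$theta[match(1:5, sec$idx)]
  expect_equal(th[1L], 0)
  expect_equal(th[2L], 90)
  expect_equal(th[3L], 180)
  expect_equal(th[4L], -acos(10 / sqrt(125)) * 180 / pi)
  expect_equal(th[5L], -90)
  expect_false(is.unsorted(sec$theta))
  # sector assignment: 5-degree bins centred on multiples of 5
  expect_equal(sec$sector[match(1L, sec$idx)], 0L)
  expect_equal(sec$sector[match(2L, sec$idx)], 18L)

  expect_warning(sec2 <- compute_angles(1:2, rp, rbind(c(0, 0, 5), c(1, -1, 0))),
                 "coincident")
  expect_equal(sec2$theta[match(1L, sec2$idx)], 0)
})

test_that("point M maximizes the normal angle with index tie-break", {
  # flat plane: all normals equal, all NOA zero, lowest vertex index wins
  v <- rbind(c(0, -10, 0), c(0.3, -11, 0), c(-0.3, -12, 0), c(30, -10, 0))
  nrm <- matrix(rep(c(0, 0, 1), each = 4L), ncol = 3L)
  mesh <- structure(list(vertices = v), class = "ibc_mesh")
  fld <- structure(list(normals = nrm, mesh = mesh), class = "ibc_curvature")
  sec <- compute_angles(1:4, list(x = 0, y = 0), v)
  m <- find_point_M(sec, fld, radius = 10)
  expect_equal(m$vertex, 1L)
  expect_true(all(m$noa[is.finite(m$noa)] == 0))

  # two candidates 15 mm apart with radius 10: no neighbours, no NOA
  v2 <- rbind(c(0, -10, 0), c(0, -25, 0))
  fld2 <- structure(list(normals = nrm[1:2, ], mesh =
                           structure(list(vertices = v2), class = "ibc_mesh")),
                    class = "ibc_curvature")
  sec2 <- compute_angles(1:2, list(x = 0, y = 0), v2)
  expect_error(find_point_M(sec2, fld2, radius = 10),
               "no intermediate sector candidates")
  expect_error(find_point_M(sec, fld, radius = 0.001), "no intermediate")
})

test_that("the intermediate point is the kmin minimizer near M", {
  v <- rbind(c(0, -10, 0), c(3, -10, 0), c(20, -10, 0))
  mesh <- structure(list(vertices = v), class = "ibc_mesh")
  fld <- structure(list(kmin = c(-0.05, -0.2, -9), mesh = mesh),
                   class = "ibc_curvature")
  # neighbour with lower kmin wins; the far better one is out of radius
  expect_equal(find_intermediate_point(1L, 1:3, fld, radius = 10), 2L)
  # M alone in its ball returns M
  expect_equal(find_intermediate_point(3L, 1:3, fld, radius = 10), 3L)
})

test_that("M and the intermediate point land on the synthetic crease", {
  ca <- quick_case(grade = 2, seed = 1)
  fld <- principal_curvatures(ca$mesh)
  cands <- suppressMessages(select_candidates(fld))
  s <- split_sides(ca$mesh)
  cand <- cands$idx[ca$mesh$vertices[cands$idx, 1L] >= s$midline]
  g <- build_block_grid(s$right, fld, 5)
  rp <- locate_reference_point(g)
  sec <- compute_angles(cand, rp, ca$mesh$vertices)
  m <- find_point_M(sec, fld, 10)
  im <- find_intermediate_point(m$vertex, cand, fld, 10)
  dM <- brute_nn_dist(ca$mesh$vertices[m$vertex, , drop = FALSE],
                      ca$crease$right)
  dI <- brute_nn_dist(ca$mesh$vertices[im, , drop = FALSE], ca$crease$right)
  expect_lt(dM, 10)
  expect_lt(dI, 2)
})

test_that("sector arc-length arithmetic matches hand values", {
  # L = (5 deg in radians) * R; R = 114.59 mm gives L = 10.0 mm
  expect_equal((5 * pi / 180) * 114.59, 10.0, tolerance = 1e-4)
})

test_that("extension picks the kmin minimum among 2L-feasible candidates", {
  # start at R = 114.59 mm below the RP, so L = 10 mm and 2L = 20 mm.
  # Sector +1 offers a low-kmin candidate 25+ mm away and a higher-kmin one
  # 8 mm away: the 8 mm candidate must win because only it satisfies 2L.
  rp <- list(x = 0, y = 0)
  v <- rbind(c(0, -114.59, 0),     # 1: start (sector 0)
             c(8, -116, 0),        # 2: sector +1, ~8 mm from start
             c(25, -130, 10),      # 3: sector +1, far (beyond 2L), kmin lowest
             c(-30, -125, 15))     # 4: sector -1, beyond 2L
  sec <- structure(list(idx = c(4L, 1L, 2L, 3L),
                        theta = c(-6, 0, 4, 6),
                        sector = c(-1L, 0L, 1L, 1L),
                        sector_deg = 5, rp = rp), class = "ibc_sectors")
  mesh <- structure(list(vertices = v), class = "ibc_mesh")
  fld <- structure(list(kmin = c(-0.1, -0.05, -0.8, -0.5), mesh = mesh),
                   class = "ibc_curvature")
  res <- extend_contour(1L, sec, fld)
  expect_true(2L %in% res$idx)     # the 8 mm candidate is selected
  expect_false(3L %in% res$idx)    # low-kmin but 2L-infeasible
  expect_equal(res$termination[["down"]], "distance>2L")
  expect_equal(res$termination[["up"]], "no-candidate")

  # with the 2L rule disabled the low-kmin far points win instead
  res2 <- extend_contour(1L, sec, fld, use_2L = FALSE)
  expect_true(all(c(3L, 4L) %in% res2$idx))
})

test_that("detected chains always satisfy the 2L constraint (re-checked)", {
  ca <- quick_case(grade = 3, seed = 2)
  det <- detect_quiet(ca$mesh)
  for (sd in c("right", "left")) {
    s <- det$sides[[sd]]
    k <- s$contour$knots
    rp <- s$rp
    # walk outward from the intermediate point in both directions
    ipos <- which(s$contour$idx == s$intermediate)
    for (dirn in c(-1L, 1L)) {
      prev <- ipos
      repeat {
        nxt <- prev + dirn
        if (nxt < 1L || nxt > nrow(k)) break
        R <- sqrt((k[prev, 1L] - rp$x)^2 + (k[prev, 2L] - rp$y)^2)
        L <- 5 * pi / 180 * R
        dd <- sqrt(sum((k[nxt, ] - k[prev, ])^2))
        expect_lt(dd, 2 * L)
        prev <- nxt
      }
    }
  }
})

test_that("contour ordering, membership and determinism invariants hold", {
  ca <- quick_case(grade = 1, seed = 3)
  det1 <- detect_quiet(ca$mesh)
  det2 <- detect_quiet(ca$mesh)
  for (sd in c("right", "left")) {
    s <- det1$sides[[sd]]
    expect_false(is.unsorted(s$contour$sector))
    expect_true(s$intermediate %in% s$contour$idx)
    expect_true(all(s$contour$idx %in% det1$candidates$idx))
    expect_identical(s$contour$knots, det2$sides[[sd]]$contour$knots)
  }
})

test_that("cubic spline fitting interpolates and degrades gracefully", {
  line <- cbind(seq(0, 30, length.out = 6), seq(0, 15, length.out = 6), 1)
  sp <- fit_spline(line, 50)
  # spline of collinear points stays on the line
  dir <- c(30, 15, 0) / sqrt(30^2 + 15^2)
  rel <- sweep(sp$samples, 2L, c(0, 0, 1))
  offaxis <- rel - outer(as.vector(rel %*% dir), dir)
  expect_lt(max(abs(offaxis)), 1e-9)

  # knots are reproduced exactly
  th <- seq(0, 355, by = 5) * pi / 180
  circ <- cbind(100 * cos(th), 100 * sin(th), 0)
  spc <- fit_spline(circ, length(th))
  param_at_knots <- spc$param
  resampled <- vapply(1:3, function(k)
    stats::spline(spc$param, circ[, k], xout = param_at_knots,
                  method = "natural")$y, numeric(length(th)))
  expect_equal(resampled, unname(circ))

  # dense samples of a circle stay within 0.1 mm radially
  spd <- fit_spline(circ, 200)
  expect_lt(max(abs(sqrt(rowSums(spd$samples[, 1:2]^2)) - 100)), 0.1)

  expect_error(fit_spline(circ[1:3, ]), "contour too short")
})
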