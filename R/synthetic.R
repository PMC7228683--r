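#' Parameters for the synthetic torso generator
#'
#' The generator emulates a cropped anterior torso ROI: a gently convex chest
#' sheet (parabolic cylinder, radius \code{chest_radius}) carrying two breast
#' mounds. Each mound is a compact-support radial bump of maximum protrusion
#' \code{protrusion} on a disk of radius \code{breast_radius}; the bump's C1
#' attachment with a curvature jump makes the lower attachment ring a genuine
#' concave crease whose position is known in closed form. Ptosis is modelled
#' as a downward in-plane shear that vanishes at the attachment ring, so the
#' crease is grade-invariant while the mound mass sags; for grades >= 1 the
#' shear is strong enough to fold the surface over (an overhang with
#' downward-facing triangles) and the lowest point of the overhang -- the
#' analytic LVP -- drops strictly below the crease. The default mound
#' centres sit high enough that the ROI's upper boundary crops the
#' attachment ring at centre angles of about +/-110 degrees: only the
#' inferior attachment arc -- the clinically annotated portion -- lies
#' inside the ROI, and contour tracing terminates at the crop boundary just
#' as it does at missing data on real cropped scans.
#'
#' Grades map to shear strength (fraction of \code{breast_radius}):
#' 0 -> 0.20 (full, no overhang), 1 -> 1.00, 2 -> 1.15, 3 -> 1.30.
#'
#' Noise emulates stereophotogrammetry surface error as a smooth band-limited
#' Gaussian random field (random cosine features) applied along vertex
#' normals; \code{noise} is its RMS amplitude in mm and \code{noise_corr} the
#' correlation length.
#'
#' @param width,height torso ROI extent in x and y, mm.
#' @param chest_radius radius of the chest-wall parabolic cylinder, mm.
#' @param breast_offset_x lateral distance of each mound centre from the
#'   midline, mm.
#' @param breast_center_y mound centre height, mm.
#' @param breast_radius attachment-ring (crease) radius, mm.
#' @param protrusion maximum anterior bump height, mm.
#' @param ptosis_grade integer 0-3.
#' @param edge grid spacing (target mesh edge length), mm.
#' @param noise RMS jitter amplitude, mm (must be < edge).
#' @param noise_corr jitter correlation length, mm.
#' @param hole optional \code{list(center = c(x, y), radius)}: faces whose
#'   vertices all fall inside the disk (in the x-y parameter plane) are
#'   removed, emulating a scan hole.
#' @param seed integer seed controlling the jitter field.
#' @return a validated parameter list of class \code{ibc_torso_params}.
#' @export
torso_params <- function(width = 300, height = 300, chest_radius = 250,
                         breast_offset_x = 80, breast_center_y = 278,
                         breast_radius = 65, protrusion = 55,
                         ptosis_grade = 0, edge = 1.5,
                         noise = 0.3, noise_corr = 20,
                         hole = NULL, seed = 1L) {
  p <- list(width = width, height = height, chest_radius = chest_radius,
            breast_offset_x = breast_offset_x,
            breast_center_y = breast_center_y,
            breast_radius = breast_radius, protrusion = protrusion,
            ptosis_grade = as.integer(ptosis_grade), edge = edge,
            noise = noise, noise_corr = noise_corr, hole = hole,
            seed = as.integer(seed))
  bad <- character()
  pos <- c("width", "height", "chest_radius", "breast_offset_x",
           "breast_center_y", "breast_radius", "protrusion", "edge",
           "noise_corr")
  for (nm in pos) if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
    bad <- c(bad, paste0(nm, " must be positive"))
  if (!p$ptosis_grade %in% 0:3) bad <- c(bad, "ptosis_grade must be 0, 1, 2 or 3")
  if (is.numeric(p$edge) && is.numeric(p$breast_radius) &&
      p$edge > p$breast_radius / 5)
    bad <- c(bad, "edge must be <= breast_radius/5 so the crease is resolvable")
  if (!is.numeric(p$noise) || p$noise < 0) bad <- c(bad, "noise must be >= 0")
  if (is.numeric(p$noise) && is.numeric(p$edge) && p$noise >= p$edge)
    bad <- c(bad, "noise must be < edge")
  if (is.numeric(p$breast_offset_x) && is.numeric(p$breast_radius) &&
      p$breast_offset_x + p$breast_radius > p$width / 2)
    bad <- c(bad, "breast does not fit inside the torso half-width")
  if (!is.null(p$hole) &&
      (!is.list(p$hole) || is.null(p$hole$center) || is.null(p$hole$radius)))
    bad <- c(bad, "hole must be list(center = c(x, y), radius = r)")
  if (length(bad)) stop("invalid torso parameters:\n  ", paste(bad, collapse = "\n  "))
  class(p) <- "ibc_torso_params"
  p
}

grade_shear <- c(`0` = 0.20, `1` = 1.00, `2` = 1.15, `3` = 1.30)

# Mound profile: paraboloid cap with a slope discontinuity at the rim. The
# attachment ring is then a true fold (dihedral crease), as the inframammary
# fold is, and its concave signature dominates any smooth concavity the
# ptosis shear adds just inside the ring.
pbump <- function(u) pmax(1 - u^2, 0)

# Shear envelope: C1 compact bump (zero value and slope at the rim), so the
# sag leaves the attachment ring and the fold dihedral grade-invariant.
bump <- function(u) ifelse(u < 1, (1 - u^2)^2, 0)
bump_d1 <- function(u) ifelse(u < 1, -4 * u * (1 - u^2), 0)

# analytic surface of one case: given parameter-plane coords, returns the
# pre-noise displaced position (x, y - shear, z)
torso_surface <- function(x, y, p) {
  z <- -x^2 / (2 * p$chest_radius)
  shear <- numeric(length(x))
  kap <- grade_shear[[as.character(p$ptosis_grade)]]
  for (sx in c(-1, 1)) {
    cx <- sx * p$breast_offset_x
    dx <- x - cx
    dy <- y - p$breast_center_y
    u <- sqrt(dx^2 + dy^2) / p$breast_radius
    z <- z + p$protrusion * pbump(u)
    shear <- shear + kap * p$breast_radius * bump(u)
  }
  cbind(x, y - shear, z)
}

# stationary point of h(u) = u + kappa*bump(u) on (0, 1/sqrt(3)): the sag
# overhang bottom. Returns NULL when the shear is too weak for an overhang.
sag_apex <- function(kappa) {
  h1 <- function(u) 1 + kappa * bump_d1(u)
  up <- 1 / sqrt(3)
  if (h1(up) >= 0) return(NULL)  # no sign change: no interior maximum
  u <- stats::uniroot(h1, c(1e-9, up), tol = 1e-12)$root
  h <- u + kappa * bump(u)
  if (h <= 1) return(NULL)       # overhang does not drop below the ring
  list(u = u, h = h)
}

#' Generate a synthetic torso case with analytic ground truth
#'
#' Builds the torso mesh for the given parameters together with the analytic
#' inferior attachment crease (one arc per side, centre angles -105 to 105
#' degrees, 1-degree sampling) and, for ptosis grades >= 1, the analytic
#' lowest visible point of each side. Ground truth is computed from the
#' continuous surface, never from the mesh; noise perturbs only the mesh.
#' Identical parameters and seed reproduce the mesh bit-for-bit.
#'
#' @param params an \code{ibc_torso_params} object (see
#'   \code{\link{torso_params}}).
#' @return an \code{ibc_case}: list with \code{mesh}, \code{crease} (list
#'   \code{right}/\code{left} of ground-truth arcs as
#'   \code{ibc_contour_points}), \code{lvp} (list \code{right}/\code{left},
#'   each a 3-vector or NULL), and \code{params}.
#' @export
generate_torso <- function(params = torso_params()) {
  if (!inherits(params, "ibc_torso_params")) params <- do.call(torso_params, params)
  p <- params
  xs <- seq(-p$width / 2, p$width / 2, by = p$edge)
  ys <- seq(0, p$height, by = p$edge)
  g <- expand.grid(x = xs, y = ys)
  v <- torso_surface(g$x, g$y, p)
  f <- grid_faces(length(xs), length(ys))
  storage.mode(f) <- "integer"

  if (!is.null(p$hole)) {
    hc <- p$hole$center
    inhole <- (g$x - hc[1L])^2 + (g$y - hc[2L])^2 < p$hole$radius^2
    fkeep <- !(inhole[f[, 1L]] & inhole[f[, 2L]] & inhole[f[, 3L]])
    f <- f[fkeep, , drop = FALSE]
    used <- logical(nrow(v))
    used[as.vector(f)] <- TRUE
    v <- v[used, , drop = FALSE]
    g <- g[used, , drop = FALSE]
    f <- matrix(cumsum(used)[f], ncol = 3L)
    storage.mode(f) <- "integer"
  }

  mesh <- ibc_mesh(v, f, provenance = "synthetic", validate = FALSE)

  if (p$noise > 0) {
    vn <- vertex_normals(mesh)
    field <- with_preserved_seed(p$seed, {
      K <- 64L
      om <- matrix(stats::rnorm(2L * K, sd = 1 / p$noise_corr), K, 2L)
      ph <- stats::runif(K, 0, 2 * pi)
      sqrt(2 / K) * p$noise *
        as.vector(cos(cbind(g$x, g$y) %*% t(om) + rep(ph, each = nrow(g))) %*%
                    rep(1, K))
    })
    mesh$vertices <- mesh$vertices + vn * field
  }

  gt <- analytic_ground_truth(p)
  structure(list(mesh = mesh, crease = gt$crease, lvp = gt$lvp, params = p),
            class = "ibc_case")
}

# Ground truth from the continuous surface (no mesh, no noise).
analytic_ground_truth <- function(p, arc_deg = 105, step_deg = 1) {
  kap <- grade_shear[[as.character(p$ptosis_grade)]]
  alpha <- seq(-arc_deg, arc_deg, by = step_deg) * pi / 180
  crease <- list()
  lvp <- list()
  for (side in c("right", "left")) {
    sx <- if (side == "right") 1 else -1
    cx <- sx * p$breast_offset_x
    xg <- cx + p$breast_radius * sin(alpha) * sx
    yg <- p$breast_center_y - p$breast_radius * cos(alpha)
    pts <- torso_surface(xg, yg, p)
    crease[[side]] <- contour_points(pts, label = "ground_truth")
    ap <- sag_apex(kap)
    if (is.null(ap)) {
      lvp[side] <- list(NULL)
    } else {
      lp <- torso_surface(cx, p$breast_center_y - ap$u * p$breast_radius, p)
      lvp[[side]] <- as.vector(lp)
    }
  }
  list(crease = crease, lvp = lvp)
}

#' @export
print.ibc_case <- function(x, ...) {
  p <- x$params
  cat(sprintf("ibc_case: ptosis grade %d, seed %d, edge %.2f mm, noise %.2f mm\n",
              p$ptosis_grade, p$seed, p$edge, p$noise))
  print(x$mesh)
  for (side in c("right", "left")) {
    lv <- x$lvp[[side]]
    cat(sprintf("  %s crease: %d ground-truth points; LVP %s\n", side,
                nrow(x$crease[[side]]),
                if (is.null(lv)) "absent (no overhang)"
                else sprintf("(%.1f, %.1f, %.1f)", lv[1L], lv[2L], lv[3L])))
  }
  invisible(x)
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
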