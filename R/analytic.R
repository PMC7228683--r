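# Analytic fixture surfaces with known principal curvatures. These are the
# oracles for the curvature estimator: sphere (k = 1/r twice), cylinder
# (1/r and 0), plane (0, 0) and saddle z = (x^2 - y^2)/c (kmax = -kmin at the
# origin).

# Regular grid triangulation over nx x ny vertices (row-major, x fastest).
# A uniform diagonal direction keeps every interior vertex at valence 6,
# which the one-ring curvature tensor integration favours (alternating
# diagonals mix valence 4 and 8 and bias the direction sampling).
grid_faces <- function(nx, ny) {
  ix <- rep(seq_len(nx - 1L), ny - 1L)
  iy <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (iy - 1L) * nx + ix
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

# Heightfield mesh z = fz(x, y) over a regular grid, CCW from +z (outward
# normal anterior).
heightfield_mesh <- function(xs, ys, fz, provenance = "synthetic") {
  g <- expand.grid(x = xs, y = ys)
  z <- fz(g$x, g$y)
  v <- cbind(g$x, g$y, z)
  f <- grid_faces(length(xs), length(ys))
  ibc_mesh(v, f, provenance = provenance, validate = FALSE)
}

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(1 + t^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_mesh <- function(v, f) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  k <- key(e[, 1L], e[, 2L])
  uk <- unique(k)
  mididx <- match(k, uk) + nrow(v)
  ue <- e[match(uk, k), , drop = FALSE]
  mid <- (v[ue[, 1L], , drop = FALSE] + v[ue[, 2L], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mididx[seq_len(nf)]
  m23 <- mididx[nf + seq_len(nf)]
  m31 <- mididx[2L * nf + seq_len(nf)]
  fnew <- rbind(cbind(f[, 1L], m12, m31),
                cbind(f[, 2L], m23, m12),
                cbind(f[, 3L], m31, m23),
                cbind(m12, m23, m31))
  list(vertices = rbind(v, mid), faces = fnew_int(fnew))
}

fnew_int <- function(f) { storage.mode(f) <- "integer"; f }

#' Generate an analytic oracle surface
#'
#' Triangulated surfaces whose principal curvatures are known in closed form
#' at every interior vertex, used to validate the curvature estimator.
#'
#' \describe{
#'   \item{sphere}{icosphere of radius \code{size}; both curvatures
#'     \code{1/size} everywhere (closed, no boundary).}
#'   \item{cylinder}{open tube of radius \code{size} about the y axis, height
#'     \code{3*size}; away from the rims \code{kmax = 1/size}, \code{kmin = 0}.}
#'   \item{plane}{flat square of half-width \code{size} at z = 0; both zero.}
#'   \item{saddle}{z = (x^2 - y^2)/(4*size) over a square of half-width
#'     \code{size}; at the origin \code{kmax = -kmin = 1/(2*size)}.}
#' }
#'
#' @param kind surface type.
#' @param size characteristic size (radius or half-width), mm.
#' @param edge target edge length, mm.
#' @return an \code{ibc_mesh}.
#' @export
generate_analytic_surface <- function(kind = c("sphere", "cylinder", "plane", "saddle"),
                                      size = 50, edge = 1.5) {
  kind <- match.arg(kind)
  stopifnot(size > 0, edge > 0)
  if (kind == "sphere") {
    ico <- icosahedron()
    # icosahedron edge ~1.05 for unit sphere; subdivision halves edges
    nsub <- max(0L, ceiling(log2(1.05 * size / edge)))
    v <- ico$vertices; f <- ico$faces
    for (i in seq_len(nsub)) {
      s <- subdivide_mesh(v, f)
      v <- s$vertices / sqrt(rowSums(s$vertices^2))
      f <- s$faces
    }
    return(ibc_mesh(v * size, f, provenance = "synthetic", validate = FALSE))
  }
  if (kind == "cylinder") {
    h <- 3 * size
    ncirc <- max(8L, round(2 * pi * size / edge))
    nh <- max(2L, round(h / edge)) + 1L
    th <- seq(0, 2 * pi, length.out = ncirc + 1L)[-(ncirc + 1L)]
    ys <- seq(-h / 2, h / 2, length.out = nh)
    v <- cbind(rep(size * sin(th), nh), rep(ys, each = ncirc),
               rep(size * cos(th), nh))
    # quad strip faces with wraparound
    i <- rep(seq_len(ncirc), nh - 1L)
    j <- rep(seq_len(nh - 1L), each = ncirc)
    inext <- ifelse(i == ncirc, 1L, i + 1L)
    v00 <- (j - 1L) * ncirc + i
    v10 <- (j - 1L) * ncirc + inext
    v01 <- j * ncirc + i
    v11 <- j * ncirc + inext
    f <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
    return(ibc_mesh(v, fnew_int(f), provenance = "synthetic", validate = TRUE))
  }
  xs <- seq(-size, size, by = edge)
  if (kind == "plane")
    return(heightfield_mesh(xs, xs, function(x, y) rep(0, length(x))))
  heightfield_mesh(xs, xs, function(x, y) (x^2 - y^2) / (4 * size))
}
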