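#' Unit normal of a single triangle
#'
#' \code{normal = a x b} for the two side vectors \code{a = v2 - v1},
#' \code{b = v3 - v1}, normalized; direction follows the winding
#' (counter-clockwise seen from outside gives the outward normal).
#'
#' @param tri 3 x 3 matrix, one vertex per row.
#' @return unit 3-vector.
#' @export
face_normal <- function(tri) {
  tri <- as.matrix(tri)
  stopifnot(nrow(tri) == 3L, ncol(tri) == 3L)
  a <- tri[2L, ] - tri[1L, ]
  b <- tri[3L, ] - tri[1L, ]
  n <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  len <- sqrt(sum(n^2))
  if (len == 0) stop("degenerate (zero-area) face")
  n / len
}

#' Unit normals of all mesh faces
#' @param mesh an \code{ibc_mesh}.
#' @return m x 3 matrix of unit normals.
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh$vertices, mesh$faces)
  len <- sqrt(rowSums(cr * cr))
  if (any(len == 0))
    stop("degenerate (zero-area) face at index ", which(len == 0)[1L])
  cr / len
}

#' Detect the lowest visible point of a breast overhang
#'
#' Faces whose outward normal lies within \code{cone_deg} of straight down
#' mark the underside of a ptotic overhang. Their vertices, filtered to lie
#' laterally (in x) strictly between the detected contour's two endpoint
#' knots, are the LVP candidates; the one with the lowest y is the LVP.
#' When no face points downward the breast has no overhang (ptosis grade 0:
#' the lowest visible contour coincides with the inframammary fold) and the
#' LVP is reported absent -- a valid result, not an error.
#'
#' The cone axis defaults to -y, the gravity axis of the coordinate
#' convention; it is configurable so alternative axis conventions can be
#' tested.
#'
#' @param mesh an \code{ibc_mesh}.
#' @param contour an \code{ibc_contour_result} for this breast (supplies the
#'   endpoint knots), or a 2-vector \code{c(xlo, xhi)} of lateral bounds.
#' @param cone_deg half-angle of the downward cone, degrees.
#' @param axis cone axis (unit direction of "down").
#' @return an \code{ibc_lvp}: list with \code{present}, \code{position}
#'   (3-vector or NULL), \code{vertex} (index or NA), \code{n_candidates}.
#' @export
detect_lvp <- function(mesh, contour, cone_deg = 10, axis = c(0, -1, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  fn <- face_normals(mesh)
  ca <- fn %*% axis
  hit <- as.vector(ca) >= cos(cone_deg * pi / 180)
  if (!any(hit))
    return(structure(list(present = FALSE, position = NULL,
                          vertex = NA_integer_, n_candidates = 0L),
                     class = "ibc_lvp"))
  vs <- unique(as.vector(mesh$faces[hit, , drop = FALSE]))
  if (inherits(contour, "ibc_contour_result")) {
    xe <- range(contour$knots[c(1L, nrow(contour$knots)), 1L])
  } else xe <- range(contour)
  x <- mesh$vertices[vs, 1L]
  vs <- vs[x > xe[1L] & x < xe[2L]]
  if (length(vs) == 0L)
    return(structure(list(present = FALSE, position = NULL,
                          vertex = NA_integer_, n_candidates = 0L),
                     class = "ibc_lvp"))
  y <- mesh$vertices[vs, 2L]
  low <- vs[y == min(y)]
  low <- low[which.min(low)]
  structure(list(present = TRUE, position = mesh$vertices[low, ],
                 vertex = low, n_candidates = length(vs)),
            class = "ibc_lvp")
}

#' @export
print.ibc_lvp <- function(x, ...) {
  if (x$present)
    cat(sprintf("ibc_lvp: (%.2f, %.2f, %.2f) mm, vertex %d (%d candidates)\n",
                x$position[1L], x$position[2L], x$position[3L], x$vertex,
                x$n_candidates))
  else cat("ibc_lvp: absent (no downward-facing overhang)\n")
  invisible(x)
}
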