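#' Angles of candidate points about the reference point
#'
#' For each candidate \eqn{p_i} the angle relative to the reference point is
#' \deqn{\theta_i = sign(x_{p_i} - x_{RP}) \arccos\!\left(
#'   \frac{v_1 \cdot v_2}{|v_1||v_2|}\right)}
#' with \eqn{v_1} along \eqn{-y} and \eqn{v_2 = (x_{p_i} - x_{RP},\,
#' y_{p_i} - y_{RP})}, in degrees in (-180, 180]: 0 straight below the RP,
#' positive toward +x. Candidates are then assigned to angular sectors of
#' \code{sector_deg} width, sector 0 centred on 0 (sector k covers
#' [5k - 2.5, 5k + 2.5) degrees at the default width).
#'
#' A candidate coincident with the RP in (x, y) has no defined angle and is
#' assigned 0 with a warning; one exactly above the RP gets +180.
#'
#' @param candidates vertex indices of this side's candidate points.
#' @param rp an \code{ibc_refpoint} (or list with \code{x}, \code{y}).
#' @param vertices the mesh vertex matrix.
#' @param sector_deg sector width, degrees.
#' @return an \code{ibc_sectors}: list with \code{idx} (candidate vertex
#'   indices sorted by angle), \code{theta} (degrees, same order),
#'   \code{sector} (integer sector id), \code{sector_deg}, \code{rp}.
#' @export
compute_angles <- function(candidates, rp, vertices, sector_deg = 5) {
  if (length(candidates) == 0L) stop("no candidates on this side")
  dx <- vertices[candidates, 1L] - rp$x
  dy <- vertices[candidates, 2L] - rp$y
  r <- sqrt(dx^2 + dy^2)
  coinc <- r == 0
  if (any(coinc))
    warning(sum(coinc), " candidate(s) coincident with RP; angle set to 0")
  cosang <- ifelse(coinc, 1, pmin(pmax(-dy / ifelse(coinc, 1, r), -1), 1))
  theta <- sign(dx) * acos(cosang) * 180 / pi
  theta[dx == 0 & dy > 0] <- 180   # directly above: +180 by convention
  theta[coinc] <- 0
  o <- order(theta, candidates)
  theta <- theta[o]
  idx <- candidates[o]
  sector <- as.integer(floor((theta + sector_deg / 2) / sector_deg))
  # fold the closed +180 endpoint into the top sector
  smax <- as.integer(floor((180 + sector_deg / 2) / sector_deg))
  sector[sector == smax] <- smax - 1L
  structure(list(idx = idx, theta = theta, sector = sector,
                 sector_deg = sector_deg, rp = rp),
            class = "ibc_sectors")
}

#' Point of largest shape change in the sector below the reference point
#'
#' Within the sector straddling 0 degrees (-2.5 to 2.5 at the default
#' width), each candidate's normal angle (NOA) is the largest angle between
#' its one-ring vertex normal and the normal of any other candidate of this
#' side within \code{radius} mm (Euclidean, 3D). The candidate with maximal
#' NOA -- the sharpest local shape change below the RP -- is point M, which
#' anchors the search for the contour's intermediate point. Candidates with
#' no neighbour inside the radius have undefined NOA (treated as -Inf); if
#' every sector-0 candidate is undefined, or the sector holds fewer than two
#' candidates, the breast is flagged undetectable.
#'
#' @param sectors an \code{ibc_sectors}.
#' @param field the \code{ibc_curvature} field (for vertex normals).
#' @param radius neighbourhood radius, mm.
#' @return list with \code{vertex} (index of M), \code{noa} (named vector of
#'   NOA values, degrees, per sector-0 candidate).
#' @export
find_point_M <- function(sectors, field, radius = 10) {
  s0 <- sectors$idx[sectors$sector == 0L]
  if (length(s0) < 2L) stop("no intermediate sector candidates")
  v <- field$mesh$vertices
  all_idx <- sectors$idx
  noa <- rep(-Inf, length(s0))
  pv <- v[all_idx, , drop = FALSE]
  nrm <- field$normals
  for (k in seq_along(s0)) {
    p <- s0[k]
    d2 <- (pv[, 1L] - v[p, 1L])^2 + (pv[, 2L] - v[p, 2L])^2 +
      (pv[, 3L] - v[p, 3L])^2
    nb <- all_idx[d2 <= radius^2 & all_idx != p]
    if (length(nb) == 0L) next
    ca <- pmin(pmax(as.vector(nrm[nb, , drop = FALSE] %*% nrm[p, ]), -1), 1)
    noa[k] <- max(acos(ca)) * 180 / pi
  }
  if (all(!is.finite(noa)))
    stop("no intermediate sector candidates (no neighbours within radius)")
  best <- which(noa == max(noa))
  names(noa) <- s0
  list(vertex = min(s0[best]), noa = noa)
}

#' Intermediate contour point near M
#'
#' The intermediate point is the candidate within \code{radius} mm of point
#' M with the minimum \code{kmin}: the most sharply concave vertex of the
#' crease near the largest shape change. It may be M itself. Ties break to
#' the smaller vertex index.
#'
#' @param m vertex index of point M.
#' @param candidates this side's candidate vertex indices.
#' @param field the \code{ibc_curvature} field.
#' @param radius neighbourhood radius, mm.
#' @return the intermediate point's vertex index.
#' @export
find_intermediate_point <- function(m, candidates, field, radius = 10) {
  v <- field$mesh$vertices
  d2 <- (v[candidates, 1L] - v[m, 1L])^2 + (v[candidates, 2L] - v[m, 2L])^2 +
    (v[candidates, 3L] - v[m, 3L])^2
  ball <- candidates[d2 <= radius^2]
  km <- field$kmin[ball]
  ball[km == min(km)][1L]
}

#' Extend the contour sector-by-sector under the 2L rule
#'
#' Starting from the intermediate point, the contour grows outward through
#' the angular sectors in both directions independently. In each next sector
#' the accepted point is the candidate with minimum \code{kmin} among those
#' whose Euclidean distance to the previously accepted point is strictly
#' less than \eqn{2L}, where \eqn{L = (5^\circ \pi / 180^\circ) R} is the
#' sector arc length at radius \eqn{R}, the in-plane (x, y) distance from
#' the RP to the previous point. \eqn{2L} is the largest plausible spacing
#' between contour points of adjacent sectors, so it rejects scattered
#' candidates off the crease. A direction terminates when its sector has no
#' candidate (\code{"no-candidate"}), none passes the 2L test
#' (\code{"distance>2L"}), or the hard angular stop is reached
#' (\code{"sector-range-exhausted"}; the breast base subtends a bounded
#' angle, so tracing beyond +/-120 degrees only ever follows artefacts).
#' Ties on minimal \code{kmin} break to the smaller vertex index.
#'
#' @param intermediate vertex index of the intermediate point.
#' @param sectors an \code{ibc_sectors}.
#' @param field the \code{ibc_curvature} field.
#' @param use_2L disable to accept the sector minimum unconditionally
#'   (diagnostic only).
#' @param max_angle_deg hard angular stop, degrees.
#' @return an \code{ibc_contour_result}: list with \code{idx} (detected
#'   vertex indices ordered by ascending angle), \code{theta},
#'   \code{sector}, \code{intermediate} (vertex index), \code{termination}
#'   (named character: down/up), \code{rp}, \code{knots} (coordinate matrix).
#' @export
extend_contour <- function(intermediate, sectors, field, use_2L = TRUE,
                           max_angle_deg = 120) {
  v <- field$mesh$vertices
  rp <- sectors$rp
  sd <- sectors$sector_deg
  pos <- match(intermediate, sectors$idx)
  if (is.na(pos)) stop("intermediate point is not a candidate of this side")
  s_int <- sectors$sector[pos]
  smax <- as.integer(floor(max_angle_deg / sd))
  acc_idx <- intermediate
  acc_sec <- s_int
  term <- c(down = NA_character_, up = NA_character_)
  for (dirn in c(1L, -1L)) {
    prev <- intermediate
    s <- s_int
    reason <- "sector-range-exhausted"
    repeat {
      s <- s + dirn
      if (abs(s) > smax) { reason <- "sector-range-exhausted"; break }
      insec <- sectors$idx[sectors$sector == s]
      if (length(insec) == 0L) { reason <- "no-candidate"; break }
      R <- sqrt((v[prev, 1L] - rp$x)^2 + (v[prev, 2L] - rp$y)^2)
      L <- (sd * pi / 180) * R
      d <- sqrt((v[insec, 1L] - v[prev, 1L])^2 +
                  (v[insec, 2L] - v[prev, 2L])^2 +
                  (v[insec, 3L] - v[prev, 3L])^2)
      ok <- if (use_2L) insec[d < 2 * L] else insec
      if (length(ok) == 0L) { reason <- "distance>2L"; break }
      km <- field$kmin[ok]
      pick <- ok[km == min(km)]
      pick <- pick[which.min(pick)]
      acc_idx <- c(acc_idx, pick)
      acc_sec <- c(acc_sec, s)
      prev <- pick
    }
    term[[if (dirn == 1L) "up" else "down"]] <- reason
  }
  o <- order(acc_sec)
  idx <- acc_idx[o]
  theta <- sectors$theta[match(idx, sectors$idx)]
  structure(list(idx = idx, theta = theta, sector = acc_sec[o],
                 intermediate = intermediate, termination = term, rp = rp,
                 knots = v[idx, , drop = FALSE]),
            class = "ibc_contour_result")
}

#' @export
print.ibc_contour_result <- function(x, ...) {
  cat(sprintf("ibc_contour_result: %d points, sectors %d..%d (%.1f to %.1f deg)\n",
              length(x$idx), min(x$sector), max(x$sector),
              min(x$theta), max(x$theta)))
  cat(sprintf("  termination: down=%s, up=%s\n",
              x$termination[["down"]], x$termination[["up"]]))
  invisible(x)
}

#' Fit a cubic spline through detected contour points
#'
#' A natural cubic spline is fitted per coordinate over the cumulative
#' chord-length parameter of the ordered points, interpolating every point
#' exactly, and sampled at \code{n_samples} evenly spaced parameter values.
#'
#' @param x an \code{ibc_contour_result}, \code{ibc_contour_points} or an
#'   ordered n x 3 coordinate matrix with n >= 4.
#' @param n_samples number of output samples along the curve.
#' @return an \code{ibc_spline}: list with \code{knots}, \code{param}
#'   (chord-length knot parameter), \code{samples} (n_samples x 3 matrix).
#' @export
fit_spline <- function(x, n_samples = 200L) {
  pts <- if (inherits(x, "ibc_contour_result")) x$knots else as.matrix(x)
  if (nrow(pts) < 4L) stop("contour too short: need >= 4 points for a cubic spline")
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive contour points must be distinct")
  param <- c(0, cumsum(seg))
  tout <- seq(0, param[length(param)], length.out = n_samples)
  samples <- vapply(1:3, function(k)
    stats::spline(param, pts[, k], xout = tout, method = "natural")$y,
    numeric(length(tout)))
  structure(list(knots = pts, param = param, samples = samples),
            class = "ibc_spline")
}
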