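#' Split a torso ROI into left and right halves
#'
#' The midline is the midpoint of the ROI's x-range; vertices with
#' \code{x >= midline} form the right half (ties go right). Side names follow
#' the image frame (the viewer's right, +x), not subject anatomy.
#'
#' @param mesh an \code{ibc_mesh}.
#' @param min_vertices a side with fewer vertices is an error (degenerate
#'   half-torso).
#' @return list with \code{right}, \code{left} (vertex index vectors) and
#'   \code{midline} (mm).
#' @export
split_sides <- function(mesh, min_vertices = 100L) {
  x <- mesh$vertices[, 1L]
  mid <- mean(range(x))
  right <- which(x >= mid)
  left <- which(x < mid)
  if (length(right) < min_vertices) stop("right side too sparse")
  if (length(left) < min_vertices) stop("left side too sparse")
  list(right = right, left = left, midline = mid)
}

#' Weighted shape-index block grid for one torso side
#'
#' Vertices of the side are binned into \code{block_size} x \code{block_size}
#' mm blocks on their (x, y) coordinates, anchored at the side's minimum
#' (x, y) corner. Each non-empty block carries the average weighted shape
#' index
#' \deqn{aveS_i = \frac{1}{n_i}\sum_j S_{ij} z_{ij}}
#' where the weight \eqn{z_{ij} = zo_{ij} - z_{min}} is the anterior
#' protrusion above the side's minimum z, so all weights are non-negative
#' and prominent convex regions (the breast mound) dominate.
#'
#' @param side_idx vertex indices of the side (from \code{\link{split_sides}}).
#' @param field an \code{ibc_curvature} with \code{S} populated.
#' @param block_size block edge, mm (default 5, chosen so a block holds a
#'   handful of vertices at typical scan resolution).
#' @return an \code{ibc_block_grid}: list with \code{ave_S} (matrix, rows =
#'   y-rows bottom-up, cols = x-cols left-to-right, NA for empty blocks),
#'   \code{cx}, \code{cy} (block centre coordinates), \code{zmin},
#'   \code{block_size}.
#' @export
build_block_grid <- function(side_idx, field, block_size = 5) {
  stopifnot(length(side_idx) > 0L, block_size > 0)
  v <- field$mesh$vertices[side_idx, , drop = FALSE]
  S <- field$S[side_idx]
  zmin <- min(v[, 3L])
  zw <- v[, 3L] - zmin
  x0 <- min(v[, 1L]); y0 <- min(v[, 2L])
  ix <- pmin(floor((v[, 1L] - x0) / block_size),
             floor((max(v[, 1L]) - x0) / block_size)) + 1L
  iy <- pmin(floor((v[, 2L] - y0) / block_size),
             floor((max(v[, 2L]) - y0) / block_size)) + 1L
  ncx <- max(ix); ncy <- max(iy)
  grp <- (iy - 1L) * ncx + ix
  sums <- rowsum(S * zw, grp)
  cnts <- rowsum(rep(1, length(grp)), grp)
  ave <- matrix(NA_real_, ncy, ncx)
  gid <- as.integer(rownames(sums))
  ave[cbind((gid - 1L) %/% ncx + 1L, (gid - 1L) %% ncx + 1L)] <- sums / cnts
  structure(list(ave_S = ave,
                 cx = x0 + (seq_len(ncx) - 0.5) * block_size,
                 cy = y0 + (seq_len(ncy) - 0.5) * block_size,
                 zmin = zmin, block_size = block_size),
            class = "ibc_block_grid")
}

#' Locate the per-breast reference point from a block grid
#'
#' Block A is the block with the largest average weighted shape index (the
#' most prominent convex region, i.e. the lower breast mound). A window of 7
#' columns (A's column +/- 3, i.e. +/- 15 mm laterally at the default block
#' size) by 10 rows above A (50 mm, A's own row excluded) is searched, and
#' the highest block with \code{ave_S > 0} becomes block B. The reference
#' point takes A's centre x and B's centre y, placing it on the mound above
#' where the lower pole starts sloping toward the chest wall. If no block in
#' the window is positive, B falls back to A itself (flat or absent mound),
#' with a warning.
#'
#' Ties for A (and for B candidates within the top row) are broken in
#' row-major order, bottom row first, leftmost first, for determinism.
#'
#' @param grid an \code{ibc_block_grid}.
#' @return an \code{ibc_refpoint}: list with \code{x}, \code{y} (mm),
#'   \code{block_a}, \code{block_b} (row/col indices and centres) and
#'   \code{fallback} flag.
#' @export
locate_reference_point <- function(grid) {
  ave <- grid$ave_S
  if (all(is.na(ave))) stop("block grid is empty")
  # row-major bottom-up leftmost tie-break: scan order = row, then column
  best <- -Inf; arow <- NA_integer_; acol <- NA_integer_
  for (r in seq_len(nrow(ave))) for (cc in seq_len(ncol(ave))) {
    val <- ave[r, cc]
    if (!is.na(val) && val > best) { best <- val; arow <- r; acol <- cc }
  }
  cols <- max(1L, acol - 3L):min(ncol(ave), acol + 3L)
  rows <- if (arow + 1L > nrow(ave)) integer() else
    (arow + 1L):min(nrow(ave), arow + 10L)
  brow <- NA_integer_; bcol <- NA_integer_
  for (r in rev(rows)) {  # highest first
    rowvals <- ave[r, cols]
    ok <- which(!is.na(rowvals) & rowvals > 0)
    if (length(ok)) { brow <- r; bcol <- cols[ok[1L]]; break }
  }
  fallback <- is.na(brow)
  if (fallback) {
    warning("no positive ave_S block above block A; reference point falls back to A")
    brow <- arow; bcol <- acol
  }
  structure(list(x = grid$cx[acol], y = grid$cy[brow],
                 block_a = list(row = arow, col = acol,
                                center = c(grid$cx[acol], grid$cy[arow]),
                                ave_S = best),
                 block_b = list(row = brow, col = bcol,
                                center = c(grid$cx[bcol], grid$cy[brow]),
                                ave_S = ave[brow, bcol]),
                 fallback = fallback),
            class = "ibc_refpoint")
}

#' @export
print.ibc_refpoint <- function(x, ...) {
  cat(sprintf("ibc_refpoint: RP = (%.1f, %.1f) mm [block A (%.1f, %.1f), block B (%.1f, %.1f)%s]\n",
              x$x, x$y, x$block_a$center[1L], x$block_a$center[2L],
              x$block_b$center[1L], x$block_b$center[2L],
              if (x$fallback) ", fallback B=A" else ""))
  invisible(x)
}
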