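#' Pipeline configuration
#'
#' All defaults are the published method's constants: 5 mm blocks, 5 degree
#' sectors, 10 mm search radii, the 2L chaining rule, a 10 degree LVP cone
#' about -y, 200 spline samples and dice thresholds 0.5-5 mm.
#'
#' @param block_size block grid edge, mm.
#' @param sector_deg angular sector width, degrees.
#' @param search_radius radius for point M / intermediate point, mm.
#' @param use_2L apply the 2L chaining constraint.
#' @param max_angle_deg hard angular stop for contour extension, degrees.
#' @param lvp_cone_deg LVP downward-cone half angle, degrees.
#' @param lvp_axis \code{"-y"} (gravity axis of the coordinate convention)
#'   or \code{"+z"} (alternative reading, testable).
#' @param spline_samples samples on the fitted contour spline.
#' @param dice_thresholds evaluation thresholds, mm.
#' @param side \code{"both"}, \code{"right"} or \code{"left"}.
#' @return a list of class \code{ibc_config}.
#' @export
ibc_config <- function(block_size = 5, sector_deg = 5, search_radius = 10,
                       use_2L = TRUE, max_angle_deg = 120,
                       lvp_cone_deg = 10, lvp_axis = c("-y", "+z"),
                       spline_samples = 200L,
                       dice_thresholds = c(0.5, 1, 2, 3, 4, 5),
                       side = c("both", "right", "left")) {
  lvp_axis <- match.arg(lvp_axis)
  side <- match.arg(side)
  stopifnot(block_size > 0, sector_deg > 0, search_radius > 0,
            max_angle_deg > 0, lvp_cone_deg >= 0, spline_samples >= 4L,
            all(dice_thresholds > 0))
  structure(list(block_size = block_size, sector_deg = sector_deg,
                 search_radius = search_radius, use_2L = use_2L,
                 max_angle_deg = max_angle_deg, lvp_cone_deg = lvp_cone_deg,
                 lvp_axis = lvp_axis, spline_samples = as.integer(spline_samples),
                 dice_thresholds = dice_thresholds, side = side),
            class = "ibc_config")
}

# canonical single-side detection; the caller guarantees `field$mesh` is
# oriented so this side is the +x half
detect_side_canonical <- function(field, cand_side, config) {
  grid <- build_block_grid(cand_side$side_vertices, field, config$block_size)
  rp <- locate_reference_point(grid)
  sectors <- compute_angles(cand_side$cand, rp, field$mesh$vertices,
                            config$sector_deg)
  m <- find_point_M(sectors, field, config$search_radius)
  im <- find_intermediate_point(m$vertex, cand_side$cand, field,
                                config$search_radius)
  contour <- extend_contour(im, sectors, field, use_2L = config$use_2L,
                            max_angle_deg = config$max_angle_deg)
  spline <- if (length(contour$idx) >= 4L)
    fit_spline(contour, config$spline_samples) else NULL
  axis <- if (config$lvp_axis == "-y") c(0, -1, 0) else c(0, 0, 1)
  lvp <- detect_lvp(field$mesh, contour, cone_deg = config$lvp_cone_deg,
                    axis = axis)
  list(rp = rp, point_M = m$vertex, intermediate = im, sectors = sectors,
       contour = contour, spline = spline, lvp = lvp, grid = grid)
}

mirror_side_result <- function(res) {
  neg1 <- function(p) { p[1L] <- -p[1L]; p }
  res$rp$x <- -res$rp$x
  res$rp$block_a$center[1L] <- -res$rp$block_a$center[1L]
  res$rp$block_b$center[1L] <- -res$rp$block_b$center[1L]
  res$contour$knots[, 1L] <- -res$contour$knots[, 1L]
  res$contour$theta <- -res$contour$theta
  res$contour$sector <- -res$contour$sector
  res$contour$rp <- res$rp
  # keep ascending-theta order after mirroring
  o <- order(res$contour$sector)
  res$contour$idx <- res$contour$idx[o]
  res$contour$theta <- res$contour$theta[o]
  res$contour$sector <- res$contour$sector[o]
  res$contour$knots <- res$contour$knots[o, , drop = FALSE]
  res$contour$termination <- res$contour$termination[c(2L, 1L)]
  names(res$contour$termination) <- c("down", "up")
  if (!is.null(res$spline)) res$spline <- fit_spline(res$contour$knots,
                                                     nrow(res$spline$samples))
  if (res$lvp$present) res$lvp$position <- neg1(res$lvp$position)
  res$sectors <- NULL
  res$grid <- NULL
  res
}

#' Detect the inferior breast-chest contour and LVP on a torso mesh
#'
#' Runs the full curvature-based pipeline: principal curvatures and shape
#' index, candidate selection, per-side reference point from the weighted
#' shape-index block grid, angular sectoring about the reference point,
#' intermediate-point estimation from normal angles, sector-by-sector
#' contour extension under the 2L rule, cubic-spline fitting, and detection
#' of the lowest visible point from downward-facing triangles.
#'
#' The right (+x) side is processed directly. The left side is processed by
#' mirroring the mesh about x = 0 (an exact floating-point operation),
#' running the identical right-side algorithm, and mirroring the results
#' back, which makes the pipeline exactly mirror-equivariant.
#'
#' Interior mesh holes inside the lower half of a processed side abort the
#' detection (the crease cannot be traced across missing surface); a side
#' can also fail individually (e.g. no concave candidates below the
#' reference point), which is recorded per side rather than raised, unless
#' both sides fail.
#'
#' @param mesh an \code{ibc_mesh} (or a file path, loaded via
#'   \code{\link{load_mesh}}).
#' @param config an \code{ibc_config}.
#' @param field optionally a precomputed \code{ibc_curvature} for
#'   \code{mesh}.
#' @return an \code{ibc_detection}: list with \code{sides} (per-side list
#'   with \code{status}, and on success \code{rp}, \code{contour},
#'   \code{spline}, \code{lvp}), \code{candidates}, \code{field},
#'   \code{config}, \code{mesh}.
#' @export
detect_ibc <- function(mesh, config = ibc_config(), field = NULL) {
  if (is.character(mesh)) mesh <- load_mesh(mesh)
  stopifnot(inherits(mesh, "ibc_mesh"))
  if (is.null(field)) field <- principal_curvatures(mesh)
  sides <- split_sides(mesh)

  loops <- detect_holes(mesh)
  holes <- Filter(function(l) !l$is_rim, loops)
  for (h in holes) {
    for (sd in c("right", "left")) {
      sv <- mesh$vertices[sides[[sd]], , drop = FALSE]
      bb <- apply(sv[, 1:2, drop = FALSE], 2L, range)
      if (h$centroid[1L] >= bb[1L, 1L] && h$centroid[1L] <= bb[2L, 1L] &&
          h$centroid[2L] >= bb[1L, 2L] &&
          h$centroid[2L] <= mean(bb[, 2L]))
        stop("hole in contour region (", sd, " side): cannot trace the contour")
    }
  }

  cands <- select_candidates(field)

  run_side <- function(side) {
    if (side == "right") {
      f <- field
      sv <- sides$right
      cand <- cands$idx[mesh$vertices[cands$idx, 1L] >= sides$midline]
    } else {
      mmesh <- mirror_x(mesh)
      f <- field
      f$mesh <- mmesh
      f$normals <- field$normals
      f$normals[, 1L] <- -f$normals[, 1L]
      sv <- sides$left
      cand <- cands$idx[mesh$vertices[cands$idx, 1L] < sides$midline]
    }
    if (length(cand) == 0L) stop("no candidates on ", side, " side")
    res <- detect_side_canonical(f, list(side_vertices = sv, cand = cand),
                                 config)
    if (side == "left") res <- mirror_side_result(res)
    res
  }

  wanted <- if (config$side == "both") c("right", "left") else config$side
  out <- list()
  for (sd in wanted) {
    r <- tryCatch(c(list(status = "detected"), run_side(sd)),
                  error = function(e) list(status = "failed",
                                           error = conditionMessage(e)))
    out[[sd]] <- r
  }
  if (all(vapply(out, `[[`, "", "status") == "failed"))
    stop("detection failed on all processed sides: ",
         paste(vapply(out, `[[`, "", "error"), collapse = "; "))
  structure(list(sides = out, candidates = cands, field = field,
                 config = config, mesh = mesh),
            class = "ibc_detection")
}

#' @export
print.ibc_detection <- function(x, ...) {
  cat(sprintf("ibc_detection: %d vertices, %s candidate points\n",
              nrow(x$mesh$vertices), length(x$candidates$idx)))
  for (sd in names(x$sides)) {
    s <- x$sides[[sd]]
    if (s$status == "failed") {
      cat(sprintf("  %s: FAILED (%s)\n", sd, s$error))
    } else {
      cat(sprintf("  %s: RP (%.1f, %.1f); %d contour points, %.1f to %.1f deg; LVP %s\n",
                  sd, s$rp$x, s$rp$y, length(s$contour$idx),
                  min(s$contour$theta), max(s$contour$theta),
                  if (s$lvp$present)
                    sprintf("(%.1f, %.1f, %.1f)", s$lvp$position[1L],
                            s$lvp$position[2L], s$lvp$position[3L])
                  else "absent"))
    }
  }
  invisible(x)
}

#' @export
summary.ibc_detection <- function(object, ...) {
  print(object)
  for (sd in names(object$sides)) {
    s <- object$sides[[sd]]
    if (s$status != "detected") next
    cat(sprintf("  %s termination: down=%s up=%s; candidates on side: %d\n",
                sd, s$contour$termination[["down"]],
                s$contour$termination[["up"]],
                length(s$sectors$idx)))
  }
  invisible(object)
}

#' Plot a detection result (anterior x-y view)
#'
#' Mesh vertices in grey, candidate points in blue, detected contour knots
#' in green with the fitted spline in orange, reference points in magenta
#' and the LVP in red, matching the customary presentation of this
#' detection task.
#'
#' @param x an \code{ibc_detection}.
#' @param max_points vertex subsample cap for the background cloud.
#' @param ... passed to \code{plot}.
#' @export
plot.ibc_detection <- function(x, max_points = 20000L, ...) {
  v <- x$mesh$vertices
  idx <- if (nrow(v) > max_points)
    seq.int(1L, nrow(v), length.out = max_points) else seq_len(nrow(v))
  graphics::plot(v[idx, 1L], v[idx, 2L], pch = ".", col = "grey70",
                 asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
  graphics::points(v[x$candidates$idx, 1L], v[x$candidates$idx, 2L],
                   pch = ".", col = "steelblue")
  for (s in x$sides) {
    if (s$status != "detected") next
    if (!is.null(s$spline))
      graphics::lines(s$spline$samples[, 1L], s$spline$samples[, 2L],
                      col = "darkorange", lwd = 2)
    graphics::points(s$contour$knots[, 1L], s$contour$knots[, 2L],
                     col = "forestgreen", pch = 16, cex = 0.6)
    graphics::points(s$rp$x, s$rp$y, col = "magenta", pch = 3, lwd = 2)
    if (s$lvp$present)
      graphics::points(s$lvp$position[1L], s$lvp$position[2L], col = "red",
                       pch = 17)
  }
  invisible(x)
}
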