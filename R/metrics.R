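#' Resample a contour to n evenly spaced spline points
#'
#' Fits a natural cubic spline over the cumulative chord-length parameter of
#' the input points (or reuses an already fitted \code{ibc_spline}) and
#' returns \code{n} samples evenly spaced in parameter. Detected and manual
#' contours of unequal length are brought to a common representation this
#' way before comparison.
#'
#' @param x an \code{ibc_contour_points}, \code{ibc_contour_result},
#'   \code{ibc_spline}, or ordered n x 3 matrix (n >= 4).
#' @param n number of samples.
#' @return n x 3 matrix of points along the curve.
#' @export
resample_contour <- function(x, n = 200L) {
  if (inherits(x, "ibc_spline")) {
    pts <- x$knots
  } else {
    pts <- if (inherits(x, "ibc_contour_result")) x$knots else as.matrix(x)
  }
  fit_spline(pts, n_samples = n)$samples
}

#' Symmetric average distance between two contour point sets
#'
#' For each point of either set the distance to the nearest point of the
#' other set is taken; the average distance is the mean of all these
#' nearest-point distances,
#' \deqn{ave_d = \frac{\sum_i d(A_i) + \sum_j d(B_j)}{|A| + |B|},}
#' which is symmetric in A and B by construction. Exact brute-force nearest
#' neighbours (full distance matrix).
#'
#' @param A,B point matrices (n x 3), non-empty.
#' @return average distance, mm.
#' @export
average_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty point set")
  D2 <- cross_dist2(A, B)
  dA <- sqrt(apply(D2, 1L, min))
  dB <- sqrt(apply(D2, 2L, min))
  (sum(dA) + sum(dB)) / (nrow(A) + nrow(B))
}

# Squared distances by explicit coordinate differences: exact for identical
# points (d(A, A) is exactly 0), unlike the norm-expansion trick.
cross_dist2 <- function(A, B) {
  D2 <- outer(A[, 1L], B[, 1L], "-")^2
  for (k in 2:ncol(A)) D2 <- D2 + outer(A[, k], B[, k], "-")^2
  D2
}

#' Threshold dice coefficient between two contour point sets
#'
#' The fraction of points (over both sets) whose nearest-other-contour
#' distance is strictly less than the threshold:
#' \deqn{Dc = num / (|A| + |B|) \in [0, 1].}
#' 1 means every point of each contour lies within the threshold of the
#' other; 0 means none does. Non-decreasing in the threshold.
#'
#' @param A,B point matrices (n x 3), non-empty.
#' @param threshold distance threshold, mm (> 0).
#' @return dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(A, B, threshold) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty point set")
  D2 <- cross_dist2(A, B)
  dA <- sqrt(apply(D2, 1L, min))
  dB <- sqrt(apply(D2, 2L, min))
  (sum(dA < threshold) + sum(dB < threshold)) / (nrow(A) + nrow(B))
}

#' Compare a detected contour against a reference contour
#'
#' Both contours are spline-resampled to \code{n} points (the detected
#' contour from its fitted spline, the reference from its raw annotation
#' points), then the symmetric average distance and the dice coefficient at
#' each threshold are computed.
#'
#' @param detected \code{ibc_spline}, \code{ibc_contour_result} or point
#'   matrix.
#' @param reference \code{ibc_contour_points} or point matrix.
#' @param thresholds dice distance thresholds, mm.
#' @param n resample count per contour.
#' @param id optional identifier carried into the report.
#' @return an \code{ibc_eval}: list with \code{ave_d} (mm), \code{dice}
#'   (named vector over thresholds), \code{n_samples}, \code{id}.
#' @export
evaluate_contours <- function(detected, reference,
                              thresholds = c(0.5, 1, 2, 3, 4, 5),
                              n = 200L, id = NULL) {
  A <- resample_contour(detected, n)
  B <- resample_contour(reference, n)
  D2 <- cross_dist2(A, B)
  dA <- sqrt(apply(D2, 1L, min))
  dB <- sqrt(apply(D2, 2L, min))
  ave_d <- (sum(dA) + sum(dB)) / (nrow(A) + nrow(B))
  dice <- vapply(thresholds, function(t) {
    if (t <= 0) stop("threshold must be > 0")
    (sum(dA < t) + sum(dB < t)) / (nrow(A) + nrow(B))
  }, 0)
  names(dice) <- as.character(thresholds)
  structure(list(ave_d = ave_d, dice = dice, n_samples = n, id = id),
            class = "ibc_eval")
}

#' @export
print.ibc_eval <- function(x, ...) {
  cat(sprintf("ibc_eval%s: ave_d = %.3f mm\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"), x$ave_d))
  cat("  dice:", paste(sprintf("%s mm: %.3f", names(x$dice), x$dice),
                       collapse = ", "), "\n")
  invisible(x)
}
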