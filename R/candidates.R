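#' Select the candidate contour point set (sPP)
#'
#' A vertex is a possible contour point when its shape index is negative
#' (concave shape) and its minimum principal curvature lies below the
#' ROI-wide mean of minimum principal curvatures:
#' \deqn{p \in sPP \iff S < 0 \;\wedge\; k_{min} < k_{mean}.}
#' The second condition removes near-flat vertices whose shape index dips
#' negative through mesh undulation alone. \code{kmean} is computed over all
#' non-rim ROI vertices (rim vertices carry crop artefacts); the membership
#' test itself is applied to every vertex.
#'
#' The set always contains scattered non-contour vertices; later stages
#' (reference point, sectoring, the 2L chaining rule) are responsible for
#' isolating the contour. Selection over the whole ROI happens once; sides
#' are split downstream because \code{kmean} is defined ROI-wide.
#'
#' @param field an \code{ibc_curvature} object with \code{S} populated.
#' @return an \code{ibc_candidates} object: list with \code{idx} (vertex
#'   indices, ascending), \code{kmean} (1/mm) and \code{fraction} of ROI
#'   vertices selected.
#' @export
select_candidates <- function(field) {
  if (is.null(field$S)) stop("shape index not populated")
  keep <- !field$boundary
  if (!any(keep)) keep <- rep(TRUE, length(field$kmin))
  kmean <- mean(field$kmin[keep])
  idx <- which(field$S < 0 & field$kmin < kmean)
  if (length(idx) == 0L)
    stop("no concave candidates: surface has no crease-like region")
  idx <- sort(idx)
  message(sprintf("sPP: %d of %d vertices (%.1f%%), kmean = %.5f /mm",
                  length(idx), length(field$S),
                  100 * length(idx) / length(field$S), kmean))
  structure(list(idx = idx, kmean = kmean,
                 fraction = length(idx) / length(field$S)),
            class = "ibc_candidates")
}

#' @export
print.ibc_candidates <- function(x, ...) {
  cat(sprintf("ibc_candidates: %d vertices (%.1f%% of ROI), kmean = %.5f /mm\n",
              length(x$idx), 100 * x$fraction, x$kmean))
  invisible(x)
}
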