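#' Triangle mesh of a torso region of interest
#'
#' Constructs and validates an \code{ibc_mesh}: a triangle surface mesh with
#' vertex coordinates in millimetres. This is the container every stage of the
#' contour pipeline operates on.
#'
#' Coordinate convention (stated here once, used everywhere): \code{+y} is
#' superior (up), \code{+z} is anterior (toward the camera), \code{+x} is the
#' subject's anatomical left / viewer's right. "Lowest", "downward" and
#' "above" in the detection functions are defined against this frame, so the
#' inferior-most point of a structure is its minimum-\code{y} point.
#'
#' Validation removes zero-area (degenerate) faces, checks face indices and
#' coordinate finiteness, and reorients the face winding to be globally
#' consistent with outward normals (anterior faces have positive mean
#' z-component). Meshes whose bounding-box diagonal is smaller than 10 are
#' assumed to be in metres and rescaled to millimetres with a warning.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices with consistent
#'   winding.
#' @param provenance character scalar: source path or \code{"synthetic"}.
#' @param validate logical; skip validation only for internally generated
#'   meshes known to be clean.
#' @return an object of class \code{ibc_mesh}: a list with elements
#'   \code{vertices}, \code{faces}, \code{provenance}.
#' @export
ibc_mesh <- function(vertices, faces, provenance = "unknown", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix of vertex indices")
  if (nrow(vertices) == 0L || nrow(faces) == 0L) stop("empty mesh")
  m <- structure(list(vertices = vertices, faces = faces,
                      provenance = as.character(provenance)[1L]),
                 class = "ibc_mesh")
  if (validate) m <- validate_mesh(m) else m
}

#' @export
print.ibc_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("ibc_mesh: %d vertices, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$faces), x$provenance))
  cat(sprintf("  bbox x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              bb[1L, 1L], bb[2L, 1L], bb[1L, 2L], bb[2L, 2L], bb[1L, 3L], bb[2L, 3L]))
  invisible(x)
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!all(is.finite(v))) stop("non-finite vertex coordinates")
  if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
  if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
    f <- f[f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L], , drop = FALSE]
  if (nrow(f) == 0L) stop("empty mesh after removing degenerate faces")
  # drop zero-area faces
  ar <- face_areas(v, f)
  if (any(ar <= 0)) f <- f[ar > 0, , drop = FALSE]
  if (nrow(f) == 0L) stop("empty mesh after removing degenerate faces")
  mesh$faces <- f
  # metre-scale detection
  bb <- apply(v, 2L, range)
  if (sqrt(sum((bb[2L, ] - bb[1L, ])^2)) < 10) {
    warning("bounding-box diagonal < 10; assuming metres, rescaling to mm")
    mesh$vertices <- v * 1000
  }
  orient_outward(mesh)
}

# cross products of the two edge vectors of every face (not normalized)
face_cross <- function(v, f) {
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

face_areas <- function(v, f) {
  cr <- face_cross(v, f)
  0.5 * sqrt(rowSums(cr * cr))
}

# Make winding globally consistent by flood fill over shared edges, then flip
# everything if the area-weighted mean normal has negative z on the anterior
# half (z above the mesh z-midpoint).
orient_outward <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nf <- nrow(f)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(ek(f[, 1L], f[, 2L]), ek(f[, 2L], f[, 3L]), ek(f[, 3L], f[, 1L]))
  eface <- rep.int(seq_len(nf), 3L)
  byedge <- split(eface, keys)
  adj <- vector("list", nf)
  for (fs in byedge) if (length(fs) == 2L) {
    adj[[fs[1L]]] <- c(adj[[fs[1L]]], fs[2L])
    adj[[fs[2L]]] <- c(adj[[fs[2L]]], fs[1L])
  }
  # directed edge sets for consistency test
  dir_edges <- function(tri) rbind(tri[c(1L, 2L)], tri[c(2L, 3L)], tri[c(3L, 1L)])
  visited <- logical(nf)
  flip <- logical(nf)
  stack <- integer(nf)
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    stack[1L] <- seed
    top <- 1L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      tri_cur <- f[cur, ]
      if (flip[cur]) tri_cur <- tri_cur[c(1L, 3L, 2L)]
      de_cur <- dir_edges(tri_cur)
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        visited[nb] <- TRUE
        tri_nb <- f[nb, ]
        de_nb <- dir_edges(tri_nb)
        # consistent orientation: the shared edge appears in opposite directions
        same_dir <- any(apply(de_cur, 1L, function(e)
          any(de_nb[, 1L] == e[1L] & de_nb[, 2L] == e[2L])))
        flip[nb] <- xor(same_dir, flip[cur])
        top <- top + 1L
        stack[top] <- nb
      }
    }
  }
  if (any(flip)) f[flip, ] <- f[flip, c(1L, 3L, 2L), drop = FALSE]
  cr <- face_cross(v, f)
  zmid <- mean(range(v[, 3L]))
  cz <- (v[f[, 1L], 3L] + v[f[, 2L], 3L] + v[f[, 3L], 3L]) / 3
  ant <- cz >= zmid
  if (!any(ant)) ant <- rep(TRUE, nrow(f))
  if (sum(cr[ant, 3L]) < 0) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  mesh$faces <- f
  mesh
}

#' Mirror a mesh about the x = 0 plane
#'
#' Negates x and flips face winding so outward orientation is preserved. The
#' operation is exact in floating point, which the left-breast processing path
#' relies on.
#'
#' @param mesh an \code{ibc_mesh}.
#' @return the mirrored \code{ibc_mesh}.
#' @export
mirror_x <- function(mesh) {
  mesh$vertices[, 1L] <- -mesh$vertices[, 1L]
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Load a triangle mesh from PLY or OBJ
#'
#' Reads ascii or binary little-endian PLY, or Wavefront OBJ restricted to
#' triangular faces, and validates the result (see \code{\link{ibc_mesh}}).
#'
#' @param path file path.
#' @param format \code{"ply"}, \code{"obj"} or \code{"auto"} (by extension).
#' @return a validated \code{ibc_mesh}.
#' @export
load_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj",
                     stop("cannot infer mesh format from extension: ", ext))
  }
  raw <- switch(format, ply = read_ply(path), obj = read_obj(path))
  ibc_mesh(raw$vertices, raw$faces, provenance = path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; nv <- NA_integer_; nf <- NA_integer_
  elements <- list()  # ordered: name -> count, props (for vertex)
  cur_el <- NULL
  vprops <- character()
  repeat {
    ln <- trimws(readLines(con, n = 1L))
    if (length(ln) == 0L) stop("unexpected end of PLY header")
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (tok[1L] == "comment") next
    if (tok[1L] == "format") fmt <- tok[2L]
    if (tok[1L] == "element") {
      cur_el <- tok[2L]
      elements[[cur_el]] <- list(count = as.integer(tok[3L]), props = list())
    }
    if (tok[1L] == "property" && !is.null(cur_el)) {
      elements[[cur_el]]$props <- c(elements[[cur_el]]$props, list(tok[-1L]))
    }
    if (tok[1L] == "end_header") break
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY lacks vertex or face element")
  nv <- elements$vertex$count
  nf <- elements$face$count
  if (nv == 0L || nf == 0L) stop("empty mesh in PLY file")
  vp <- vapply(elements$vertex$props, function(p) p[2L], "")
  ixyz <- match(c("x", "y", "z"), vp)
  if (anyNA(ixyz)) stop("PLY vertex element lacks x/y/z")
  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    vlines <- txt[seq_len(nv)]
    flines <- txt[nv + seq_len(nf)]
    vmat <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                   nrow = nv, byrow = TRUE)
    verts <- vmat[, ixyz, drop = FALSE]
    ftoks <- strsplit(trimws(flines), "\\s+")
    cnt <- vapply(ftoks, function(t) as.integer(t[1L]), 0L)
    if (any(cnt != 3L))
      stop("non-triangular face in PLY (face ", which(cnt != 3L)[1L], ")")
    faces <- matrix(as.integer(unlist(lapply(ftoks, function(t) t[2:4]))),
                    ncol = 3L, byrow = TRUE) + 1L
  } else if (fmt == "binary_little_endian") {
    type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    rd <- function(type, n) {
      sz <- type_size[[type]]
      what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
      readBin(con, what, n = n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    vtypes <- vapply(elements$vertex$props, function(p) p[1L], "")
    if (length(unique(vtypes)) == 1L) {
      vall <- rd(vtypes[1L], nv * length(vtypes))
      vmat <- matrix(vall, nrow = nv, byrow = TRUE)
    } else {
      vmat <- matrix(0, nv, length(vtypes))
      for (i in seq_len(nv)) for (j in seq_along(vtypes))
        vmat[i, j] <- rd(vtypes[j], 1L)
    }
    verts <- vmat[, ixyz, drop = FALSE]
    fp <- elements$face$props[[1L]]
    if (fp[1L] != "list") stop("unsupported PLY face property")
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      k <- rd(fp[2L], 1L)
      if (k != 3L) stop("non-triangular face in PLY (face ", i, ")")
      faces[i, ] <- rd(fp[3L], 3L)
    }
    faces <- faces + 1L
  } else stop("unsupported PLY format: ", fmt)
  list(vertices = verts, faces = faces)
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  vlines <- txt[startsWith(txt, "v ")]
  flines <- txt[startsWith(txt, "f ")]
  if (!length(vlines) || !length(flines)) stop("empty mesh in OBJ file")
  verts <- matrix(as.numeric(unlist(lapply(strsplit(vlines, "\\s+"),
                                           function(t) t[2:4]))),
                  ncol = 3L, byrow = TRUE)
  ftoks <- strsplit(flines, "\\s+")
  nvert <- vapply(ftoks, length, 0L) - 1L
  if (any(nvert != 3L))
    stop("non-triangular face in OBJ (face ", which(nvert != 3L)[1L],
         " has ", nvert[which(nvert != 3L)[1L]], " vertices)")
  idx <- vapply(ftoks, function(t) {
    as.integer(vapply(strsplit(t[2:4], "/"), `[`, "", 1L))
  }, integer(3L))
  list(vertices = verts, faces = t(idx))
}

#' Write a mesh to PLY (ascii) or OBJ
#'
#' @param mesh an \code{ibc_mesh}.
#' @param path output path.
#' @param format \code{"ply"}, \code{"obj"} or \code{"auto"} (by extension).
#' @param digits coordinate precision for the text formats.
#' @param vertex_scalars optional named list of per-vertex numeric vectors
#'   written as extra PLY vertex properties (e.g. shape index for
#'   pseudo-colour inspection); ignored for OBJ.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj"),
                       digits = 6L, vertex_scalars = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), ply = "ply", obj = "obj",
                     stop("cannot infer mesh format from extension"))
  v <- mesh$vertices
  f <- mesh$faces
  fmtnum <- function(x) formatC(x, digits = digits, format = "f", drop0trailing = TRUE)
  if (format == "ply") {
    extra <- ""
    vtab <- cbind(fmtnum(v[, 1L]), fmtnum(v[, 2L]), fmtnum(v[, 3L]))
    if (!is.null(vertex_scalars)) {
      for (nm in names(vertex_scalars)) {
        extra <- paste0(extra, sprintf("property float %s\n", nm))
        vtab <- cbind(vtab, fmtnum(vertex_scalars[[nm]]))
      }
    }
    hdr <- paste0("ply\nformat ascii 1.0\ncomment ibcontour\n",
                  sprintf("element vertex %d\n", nrow(v)),
                  "property float x\nproperty float y\nproperty float z\n",
                  extra,
                  sprintf("element face %d\n", nrow(f)),
                  "property list uchar int vertex_indices\nend_header")
    vl <- do.call(paste, c(split(vtab, col(vtab)), sep = " "))
    fl <- paste(3L, f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
    writeLines(c(hdr, vl, fl), path)
  } else {
    vl <- paste("v", fmtnum(v[, 1L]), fmtnum(v[, 2L]), fmtnum(v[, 3L]))
    fl <- paste("f", f[, 1L], f[, 2L], f[, 3L])
    writeLines(c("# ibcontour", vl, fl), path)
  }
  invisible(path)
}

#' Axis-aligned region-of-interest crop
#'
#' Keeps vertices inside the box and faces whose three vertices all survive;
#' faces are reindexed. Stands in for the manual torso ROI crop used with
#' clinical scans.
#'
#' @param mesh an \code{ibc_mesh}.
#' @param box numeric vector \code{c(xmin, xmax, ymin, ymax, zmin, zmax)} in mm.
#' @return the cropped \code{ibc_mesh}.
#' @export
crop_roi <- function(mesh, box) {
  stopifnot(length(box) == 6L)
  if (any(box[c(1L, 3L, 5L)] >= box[c(2L, 4L, 6L)]))
    stop("RoiBox requires min < max on each axis")
  v <- mesh$vertices
  keep <- v[, 1L] >= box[1L] & v[, 1L] <= box[2L] &
    v[, 2L] >= box[3L] & v[, 2L] <= box[4L] &
    v[, 3L] >= box[5L] & v[, 3L] <= box[6L]
  if (!any(keep)) stop("ROI does not intersect mesh")
  newid <- cumsum(keep)
  f <- mesh$faces
  fok <- keep[f[, 1L]] & keep[f[, 2L]] & keep[f[, 3L]]
  f <- f[fok, , drop = FALSE]
  if (nrow(f) == 0L) stop("ROI does not intersect mesh")
  used <- logical(nrow(v))
  used[as.vector(f)] <- TRUE
  keep2 <- keep & used
  newid <- cumsum(keep2)
  f2 <- matrix(newid[f], ncol = 3L)
  ibc_mesh(v[keep2, , drop = FALSE], f2, provenance = mesh$provenance,
           validate = FALSE)
}

boundary_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  tab <- table(key)
  single <- names(tab)[tab == 1L]
  e[match(single, key), , drop = FALSE]
}

#' Detect open boundary loops (mesh rim and holes)
#'
#' A boundary edge is an edge with exactly one incident face. Boundary edges
#' are chained into closed loops; an open patch has at least one loop (its
#' outer rim), and any further loops are interior holes. The loop with the
#' largest bounding-box diagonal is labelled the rim.
#'
#' @param mesh an \code{ibc_mesh}.
#' @return list of loops; each loop is a list with \code{vertices} (ordered
#'   vertex indices), \code{centroid}, \code{extent} (bbox diagonal, mm) and
#'   \code{is_rim}.
#' @export
detect_holes <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L) return(list())
  nxt <- split(c(be[, 2L], be[, 1L]), c(be[, 1L], be[, 2L]))
  used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  loops <- list()
  for (i in seq_len(nrow(be))) {
    k0 <- ekey(be[i, 1L], be[i, 2L])
    if (!is.null(used[[k0]])) next
    loop <- c(be[i, 1L], be[i, 2L])
    used[[k0]] <- TRUE
    closed <- FALSE
    while (!closed) {
      cur <- loop[length(loop)]
      cands <- nxt[[as.character(cur)]]
      stepped <- FALSE
      for (cn in cands) {
        k <- ekey(cur, cn)
        if (is.null(used[[k]])) {
          used[[k]] <- TRUE
          stepped <- TRUE
          if (cn == loop[1L]) closed <- TRUE else loop <- c(loop, cn)
          break
        }
      }
      if (!stepped) break  # open chain (non-manifold rim); report as-is
    }
    loops[[length(loops) + 1L]] <- loop
  }
  v <- mesh$vertices
  out <- lapply(loops, function(lp) {
    pts <- v[lp, , drop = FALSE]
    bb <- apply(pts, 2L, range)
    list(vertices = lp,
         centroid = colMeans(pts),
         extent = sqrt(sum((bb[2L, ] - bb[1L, ])^2)),
         is_rim = FALSE)
  })
  if (length(out)) {
    ext <- vapply(out, `[[`, 0, "extent")
    out[[which.max(ext)]]$is_rim <- TRUE
  }
  out
}

#' Read a contour annotation file
#'
#' Plain text, one "x y z" triple (mm) per line; lines starting with '#' are
#' comments. At least 4 points are required (the minimum for cubic-spline
#' resampling) and consecutive points must be distinct.
#'
#' @param path file path.
#' @param label annotation label, e.g. \code{"manual"} or \code{"ground_truth"}.
#' @return an \code{ibc_contour_points} object: matrix n x 3 with attribute
#'   \code{label}.
#' @export
read_contour <- function(path, label = "manual") {
  txt <- trimws(readLines(path, warn = FALSE))
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  if (!length(txt)) stop("no points in contour file: ", path)
  pts <- matrix(as.numeric(unlist(strsplit(txt, "[[:space:],]+"))), ncol = 3L,
                byrow = TRUE)
  contour_points(pts, label = label)
}

#' Construct a contour annotation from a point matrix
#' @param pts numeric n x 3 matrix (mm), ordered along the contour.
#' @param label annotation label.
#' @return an \code{ibc_contour_points} object.
#' @export
contour_points <- function(pts, label = "manual") {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("contour points must be n x 3")
  if (nrow(pts) < 4L) stop("contour too short: need >= 4 points")
  d <- rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)
  if (any(d == 0)) stop("consecutive contour points must be distinct")
  structure(pts, label = label, class = c("ibc_contour_points", "matrix", "array"))
}

#' Write a contour annotation file
#' @param pts n x 3 matrix of points (mm).
#' @param path output path.
#' @param digits coordinate precision.
#' @return \code{path}, invisibly.
#' @export
write_contour <- function(pts, path, digits = 6L) {
  pts <- as.matrix(pts)
  l <- attr(pts, "label")
  hdr <- sprintf("# ibcontour contour%s", if (is.null(l)) "" else paste0(" (", l, ")"))
  fmtnum <- function(x) formatC(x, digits = digits, format = "f", drop0trailing = TRUE)
  writeLines(c(hdr, paste(fmtnum(pts[, 1L]), fmtnum(pts[, 2L]), fmtnum(pts[, 3L]))),
             path)
  invisible(path)
}
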