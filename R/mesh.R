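#' Triangle surface mesh
#'
#' The basic container for a triangulated surface: an `n x 3` matrix of
#' vertex coordinates (mm) and an `m x 3` integer matrix of 1-based vertex
#' indices, one row per triangular facet. A mesh read from STL is a
#' "triangle soup" (three private vertices per facet); [weld_vertices()]
#' merges coincident vertices and computes the one-ring adjacency and
#' boundary flags that curvature computations need.
#'
#' @param vertices Numeric matrix with 3 columns (x, y, z in mm).
#' @param faces Integer matrix with 3 columns of vertex indices in
#'   `[1, nrow(vertices)]`.
#' @param welded Logical; `TRUE` once coincident vertices have been merged
#'   and adjacency computed.
#'
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces`, `welded`, and (after welding) `vertex_faces`
#'   (list of incident face indices per vertex) and `boundary` (logical
#'   per vertex, `TRUE` iff some incident edge belongs to exactly one face).
#' @export
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    matrix(c(1L, 2L, 3L), nrow = 1))
#' m
triangle_mesh <- function(vertices, faces, welded = FALSE) {
  vertices <- as.matrix(vertices)
  if (length(vertices) == 0) {
    vertices <- matrix(numeric(0), ncol = 3)
  }
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) {
    stop_dentalign("dentalign_error_format", "vertices must have 3 columns")
  }
  faces <- as.matrix(faces)
  if (length(faces) == 0) {
    faces <- matrix(integer(0), ncol = 3)
  }
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3) {
    stop_dentalign("dentalign_error_format", "faces must have 3 columns")
  }
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop_dentalign("dentalign_error_format",
                   "face indices out of range [1, vertex_count]")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(
    list(vertices = vertices, faces = faces, welded = isTRUE(welded)),
    class = "triangle_mesh"
  )
  if (isTRUE(welded)) {
    m <- compute_adjacency(m)
  }
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh> %d vertices, %d faces (%s)\n",
    nrow(x$vertices), nrow(x$faces),
    if (x$welded) "welded" else "triangle soup"
  ))
  if (x$welded && nrow(x$vertices) > 0) {
    cat(sprintf("  boundary vertices: %d\n", sum(x$boundary)))
  }
  invisible(x)
}

# One-ring adjacency and boundary flags.
compute_adjacency <- function(mesh) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  vf <- vector("list", nv)
  if (nf > 0) {
    idx <- as.vector(mesh$faces)                  # 3 nf vertex ids
    fid <- rep(seq_len(nf), times = 3)
    ord <- order(idx, fid)
    vf_split <- split(fid[ord], idx[ord])
    vf[as.integer(names(vf_split))] <- vf_split
  }
  mesh$vertex_faces <- vf

  boundary <- rep(FALSE, nv)
  if (nf > 0) {
    ea <- rbind(mesh$faces[, c(1, 2), drop = FALSE],
                mesh$faces[, c(2, 3), drop = FALSE],
                mesh$faces[, c(3, 1), drop = FALSE])
    lo <- pmin(ea[, 1], ea[, 2])
    hi <- pmax(ea[, 1], ea[, 2])
    key <- paste(lo, hi)
    cnt <- table(key)
    open_edges <- names(cnt)[cnt == 1L]
    if (length(open_edges) > 0) {
      parts <- strsplit(open_edges, " ", fixed = TRUE)
      vids <- unique(as.integer(unlist(parts)))
      boundary[vids] <- TRUE
    }
  }
  mesh$boundary <- boundary
  mesh
}

# Per-face areas (mm^2) via the cross-product formula.
face_areas <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(numeric(0))
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Unit facet normals from counter-clockwise vertex order; zero-area faces
# get a zero normal.
face_normals <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(matrix(numeric(0), ncol = 3))
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  ok <- len > 0
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n[!ok, ] <- 0
  n
}

# Area-weighted per-vertex normals (used for surface-normal noise).
vertex_normals <- function(mesh) {
  nv <- nrow(mesh$vertices)
  fn <- face_normals(mesh)
  fa <- face_areas(mesh)
  out <- matrix(0, nv, 3)
  f <- mesh$faces
  for (c_ in 1:3) {
    w <- fn * fa
    out[, 1] <- out[, 1] + rowsum_safe(w[, 1], f[, c_], nv)
    out[, 2] <- out[, 2] + rowsum_safe(w[, 2], f[, c_], nv)
    out[, 3] <- out[, 3] + rowsum_safe(w[, 3], f[, c_], nv)
  }
  len <- sqrt(rowSums(out^2))
  ok <- len > 0
  out[ok, ] <- out[ok, , drop = FALSE] / len[ok]
  out
}

# Sum `x` into `n` bins given by `group` (1-based), returning a length-n
# vector with zeros for empty bins.
rowsum_safe <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Euler characteristic of a welded mesh
#'
#' Computes V - E + F; equals 2 for a closed genus-0 surface.
#'
#' @param mesh A welded [triangle_mesh()].
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  ea <- rbind(f[, c(1, 2), drop = FALSE],
              f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  n_edges <- length(unique(key))
  nrow(mesh$vertices) - n_edges + nrow(f)
}

#' Tidy a triangle mesh into a vertex table
#'
#' @param x A [triangle_mesh()].
#' @param ... Unused.
#' @return A tibble with one row per vertex: `vertex`, `x`, `y`, `z` and,
#'   for welded meshes, `boundary`.
#' @export
tidy.triangle_mesh <- function(x, ...) {
  out <- tibble::tibble(
    vertex = seq_len(nrow(x$vertices)),
    x = x$vertices[, 1], y = x$vertices[, 2], z = x$vertices[, 3]
  )
  if (x$welded) out$boundary <- x$boundary
  out
}
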