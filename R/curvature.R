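#' Interior face angles at a vertex
#'
#' Returns one angle per face incident to vertex `v`: the interior angle
#' of that face at `v`, in radians, following the incident-face
#' enumeration order (ascending face index). These are the angles whose
#' deficit from `2*pi` defines the discrete Gaussian curvature.
#'
#' @param mesh A welded [triangle_mesh()].
#' @param v Vertex index.
#' @return Numeric vector of angles (radians), one per incident face.
#' @export
vertex_angles <- function(mesh, v) {
  stopifnot(inherits(mesh, "triangle_mesh"), mesh$welded)
  v <- as.integer(v)
  stopifnot(length(v) == 1, v >= 1, v <= nrow(mesh$vertices))
  fids <- mesh$vertex_faces[[v]]
  if (is.null(fids) || length(fids) == 0) {
    stop_dentalign("dentalign_error_geometry",
                   sprintf("vertex %d is isolated (no incident faces)", v))
  }
  vapply(fids, function(fi) {
    tri <- mesh$faces[fi, ]
    others <- tri[tri != v]
    p0 <- mesh$vertices[v, ]
    e1 <- mesh$vertices[others[1], ] - p0
    e2 <- mesh$vertices[others[2], ] - p0
    interior_angle(e1, e2)
  }, numeric(1))
}

interior_angle <- function(e1, e2) {
  n1 <- sqrt(sum(e1^2))
  n2 <- sqrt(sum(e2^2))
  if (n1 == 0 || n2 == 0) {
    stop_dentalign("dentalign_error_geometry",
                   "degenerate edge (zero length) in angle computation")
  }
  acos(max(-1, min(1, sum(e1 * e2) / (n1 * n2))))
}

#' Discrete Gaussian curvature of a vertex
#'
#' Angle-deficit curvature: `K = (2*pi - sum(theta_j)) / A`, where
#' `theta_j` are the interior face angles at the vertex and `A` is the
#' total area of its one-ring faces. Units are mm^-2, so curvature
#' thresholds are mesh-scale dependent (`K` scales as `1/s^2` under
#' uniform scaling by `s`).
#'
#' By default `A` is the full one-ring area, as the deficit formula is
#' usually stated for surface meshes; `area = "barycentric"` divides by
#' `A/3` instead (the barycentric lumped area used by cotangent-style
#' estimators), which converges to the pointwise Gaussian curvature on
#' refined meshes.
#'
#' Boundary vertices lack a full ring, so the deficit from `2*pi` is not
#' meaningful there; they raise an error unless `boundary_ok = TRUE`, in
#' which case the diagnostic value `(pi - sum(theta_j)) / A` is returned.
#'
#' @param mesh A welded [triangle_mesh()].
#' @param v Vertex index.
#' @param area `"one_ring"` (default) or `"barycentric"`.
#' @param boundary_ok Allow boundary vertices (diagnostic deficit from
#'   `pi`); default `FALSE`.
#' @return Curvature in mm^-2.
#' @export
#' @examples
#' # apex of a regular unit tetrahedron: deficit pi over one-ring 3*sqrt(3)/4
#' tet <- weld_vertices(tetrahedron_mesh())
#' vertex_curvature(tet, 1)          # 4*pi/(3*sqrt(3)) ~ 2.4184
vertex_curvature <- function(mesh, v, area = c("one_ring", "barycentric"),
                             boundary_ok = FALSE) {
  area <- match.arg(area)
  stopifnot(inherits(mesh, "triangle_mesh"), mesh$welded)
  if (mesh$boundary[v] && !boundary_ok) {
    stop_dentalign(
      "dentalign_error_geometry",
      sprintf("vertex %d is on the boundary; angle-deficit curvature needs a full ring (set boundary_ok = TRUE for the diagnostic value)", v)
    )
  }
  th <- vertex_angles(mesh, v)
  a <- sum(face_areas(mesh)[mesh$vertex_faces[[v]]])
  if (a <= 0) {
    stop_dentalign("dentalign_error_geometry",
                   sprintf("vertex %d has zero one-ring area", v))
  }
  if (area == "barycentric") a <- a / 3
  full <- if (mesh$boundary[v]) pi else 2 * pi
  (full - sum(th)) / a
}

#' Curvature table for every vertex
#'
#' Vectorized angle-deficit curvature over the whole mesh. Boundary
#' vertices are reported with `NA` curvature by default (they lack a full
#' ring); with `boundary = "diagnostic"` they get the open-ring deficit
#' `(pi - sum(theta)) / A`.
#'
#' @param mesh A welded [triangle_mesh()].
#' @param area `"one_ring"` (default) or `"barycentric"`, see
#'   [vertex_curvature()].
#' @param boundary `"exclude"` (default; `NA` curvature) or
#'   `"diagnostic"`.
#' @return A tibble with one row per vertex: `vertex`, `x`, `y`, `z`,
#'   `boundary`, `angle_sum` (radians), `deficit` (radians; from `2*pi`
#'   interior, from `pi` on the boundary), `ring_area` (mm^2),
#'   `curvature` (mm^-2).
#' @export
all_curvatures <- function(mesh, area = c("one_ring", "barycentric"),
                           boundary = c("exclude", "diagnostic")) {
  area <- match.arg(area)
  boundary <- match.arg(boundary)
  stopifnot(inherits(mesh, "triangle_mesh"), mesh$welded)
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  V <- mesh$vertices

  angle_sum <- numeric(nv)
  ring_area <- numeric(nv)
  if (nrow(f) > 0) {
    fa <- face_areas(mesh)
    for (c_ in 1:3) {
      i0 <- f[, c_]
      i1 <- f[, c_ %% 3 + 1]
      i2 <- f[, (c_ + 1) %% 3 + 1]
      e1 <- V[i1, , drop = FALSE] - V[i0, , drop = FALSE]
      e2 <- V[i2, , drop = FALSE] - V[i0, , drop = FALSE]
      dot <- rowSums(e1 * e2)
      nn <- sqrt(rowSums(e1^2) * rowSums(e2^2))
      ang <- acos(pmax(-1, pmin(1, dot / nn)))
      angle_sum <- angle_sum + rowsum_safe(ang, i0, nv)
      ring_area <- ring_area + rowsum_safe(fa, i0, nv)
    }
  }

  full <- ifelse(mesh$boundary, pi, 2 * pi)
  deficit <- full - angle_sum
  a_eff <- if (area == "barycentric") ring_area / 3 else ring_area
  curv <- ifelse(a_eff > 0, deficit / a_eff, NA_real_)
  if (boundary == "exclude") curv[mesh$boundary] <- NA_real_

  tibble::tibble(
    vertex = seq_len(nv),
    x = V[, 1], y = V[, 2], z = V[, 3],
    boundary = mesh$boundary,
    angle_sum = angle_sum,
    deficit = deficit,
    ring_area = ring_area,
    curvature = curv
  )
}

#' Extract curvature-thresholded feature points
#'
#' Marks as feature points the interior vertices whose angle-deficit
#' curvature exceeds the threshold `alpha` (mm^-2). The default predicate
#' is the one-sided `K > alpha`; `signed = TRUE` selects `|K| > alpha`
#' instead, so that saddle regions (negative deficit) are kept too.
#' Boundary vertices are never selected.
#'
#' @param mesh A welded [triangle_mesh()].
#' @param alpha Curvature threshold in mm^-2, `> 0`. Default `0.01`.
#' @param signed If `TRUE` select on `|K| > alpha`; default `FALSE`
#'   (`K > alpha`).
#' @param area Passed to [all_curvatures()].
#' @return An object of class `feature_set`: a list with `table` (tibble
#'   `vertex`, `x`, `y`, `z`, `curvature`, indices unique and ascending),
#'   `alpha`, `signed`, and `mesh` (the source mesh).
#' @export
extract_features <- function(mesh, alpha = 0.01, signed = FALSE,
                             area = c("one_ring", "barycentric")) {
  stopifnot(alpha > 0)
  curv <- all_curvatures(mesh, area = match.arg(area))
  sel <- if (signed) abs(curv$curvature) > alpha else curv$curvature > alpha
  sel[is.na(sel)] <- FALSE
  tab <- curv[sel, c("vertex", "x", "y", "z", "curvature")]
  structure(
    list(table = tab, alpha = alpha, signed = signed, mesh = mesh),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "<feature_set> %d feature points (alpha = %g, predicate %s)\n",
    nrow(x$table), x$alpha,
    if (x$signed) "|K| > alpha" else "K > alpha"
  ))
  invisible(x)
}

#' @describeIn extract_features Tidy a feature set into its vertex table.
#' @param x A `feature_set`.
#' @param ... Unused.
#' @export
tidy.feature_set <- function(x, ...) x$table

# Coordinates of the feature points as a matrix.
feature_points <- function(fs) {
  as.matrix(fs$table[, c("x", "y", "z")])
}

#' Write a feature set to JSON
#'
#' One record per feature point: `vertex_index`, `position` (x, y, z in
#' mm) and `curvature` (mm^-2), plus the threshold used.
#'
#' @param fs A `feature_set` from [extract_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_json <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  obj <- list(
    alpha = fs$alpha,
    signed = fs$signed,
    features = lapply(seq_len(nrow(fs$table)), function(i) {
      list(
        vertex_index = fs$table$vertex[i],
        position = c(fs$table$x[i], fs$table$y[i], fs$table$z[i]),
        curvature = fs$table$curvature[i]
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
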