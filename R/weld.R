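#' Weld coincident mesh vertices
#'
#' Merges vertices that lie within `tol` of each other, reindexes faces,
#' drops faces that become degenerate (repeated vertex index, or area
#' below `1e-12` mm^2), and computes one-ring adjacency and per-vertex
#' boundary flags. STL stores disconnected facets, so welding is required
#' before any connectivity-based computation (curvature, boundary
#' detection).
#'
#' Merging is found by repeated nearest-neighbour rounds (k-d tree) with
#' union-find: pairs at exact Euclidean distance `<= tol` are unioned
#' until no two surviving representatives are within `tol`. A merged
#' cluster keeps the coordinates of its lowest-index member, so welding a
#' welded mesh is the identity.
#'
#' @param mesh A [triangle_mesh()] (soup or welded).
#' @param tol Weld tolerance in mm (default `1e-6`); vertices at distance
#'   `<= tol` are merged. Must be `>= 0`.
#' @return A welded [triangle_mesh()] with adjacency and boundary flags.
#' @export
#' @examples
#' soup <- read_stl(write_stl(cube_mesh_soup(), tempfile(fileext = ".stl")))
#' welded <- weld_vertices(soup)
#' nrow(welded$vertices)  # 8
weld_vertices <- function(mesh, tol = 1e-6) {
  stopifnot(inherits(mesh, "triangle_mesh"), tol >= 0)
  v <- mesh$vertices
  nv <- nrow(v)
  if (nv == 0) {
    return(triangle_mesh(v, mesh$faces, welded = TRUE))
  }

  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  reps <- seq_len(nv)
  repeat {
    if (length(reps) < 2) break
    nn <- RANN::nn2(v[reps, , drop = FALSE], v[reps, , drop = FALSE], k = 2)
    close_i <- which(nn$nn.dists[, 2] <= tol)
    if (length(close_i) == 0) break
    for (i in close_i) {
      a <- find(reps[i])
      b <- find(reps[nn$nn.idx[i, 2]])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    reps <- reps[vapply(reps, find, 1L) == reps]
  }

  root <- vapply(seq_len(nv), find, 1L)
  keep <- sort(unique(root))
  new_id <- integer(nv)
  new_id[keep] <- seq_along(keep)
  map <- new_id[root]

  new_v <- v[keep, , drop = FALSE]
  f <- mesh$faces
  if (nrow(f) > 0) {
    new_f <- matrix(map[f], ncol = 3)
    ok <- new_f[, 1] != new_f[, 2] & new_f[, 2] != new_f[, 3] &
      new_f[, 1] != new_f[, 3]
    new_f <- new_f[ok, , drop = FALSE]
    tmp <- triangle_mesh(new_v, new_f)
    areas <- face_areas(tmp)
    nondeg <- areas >= 1e-12
    n_dropped <- sum(!ok) + sum(!nondeg)
    if (n_dropped > 0) {
      message(sprintf("weld_vertices: dropped %d degenerate face(s)",
                      n_dropped))
    }
    new_f <- new_f[nondeg, , drop = FALSE]
  } else {
    new_f <- f
  }
  triangle_mesh(new_v, new_f, welded = TRUE)
}
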