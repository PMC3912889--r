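#' Closest points on a mesh surface
#'
#' For each query point, finds the exactly closest point on the
#' triangulated surface (not merely the closest vertex). Candidate faces
#' are the ones incident to the `k` nearest vertices (k-d tree); the
#' exact point-to-triangle distance is then minimized over candidates.
#' On well-shaped meshes the true closest face is incident to one of the
#' nearest vertices, so the result is exact for practical purposes while
#' staying fast.
#'
#' @param mesh A welded [triangle_mesh()].
#' @param points Query points (n x 3).
#' @param k Number of nearest vertices whose incident faces are
#'   considered (default 3).
#' @return A list: `points` (n x 3 projections onto the surface),
#'   `distance` (mm), `face` (face index of each projection).
#' @export
closest_point_on_mesh <- function(mesh, points, k = 3) {
  stopifnot(inherits(mesh, "triangle_mesh"), mesh$welded)
  P <- as.matrix(points)
  n <- nrow(P)
  # large batches are processed in blocks to bound peak memory
  if (n > 20000) {
    out_p <- matrix(NA_real_, n, 3)
    out_d <- numeric(n)
    out_f <- integer(n)
    starts <- seq(1L, n, by = 20000L)
    for (s in starts) {
      e <- min(s + 19999L, n)
      blk <- closest_point_on_mesh(mesh, P[s:e, , drop = FALSE], k = k)
      out_p[s:e, ] <- blk$points
      out_d[s:e] <- blk$distance
      out_f[s:e] <- blk$face
    }
    return(list(points = out_p, distance = out_d, face = out_f))
  }
  k <- min(k, nrow(mesh$vertices))
  nn <- RANN::nn2(mesh$vertices, P, k = k)

  # candidate (point, face) pairs: faces incident to the k nearest
  # vertices, assembled without a per-point loop
  flat <- mesh$vertex_faces[as.vector(t(nn$nn.idx))]
  lens <- lengths(flat)
  pid <- rep(rep(seq_len(n), each = k), times = lens)
  fid <- unlist(flat)
  dup <- duplicated(pid * (nrow(mesh$faces) + 1) + fid)
  pid <- pid[!dup]
  fid <- fid[!dup]

  A <- mesh$vertices[mesh$faces[fid, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[fid, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[fid, 3], , drop = FALSE]
  X <- P[pid, , drop = FALSE]

  proj <- point_triangle_closest(X, A, B, C)
  d2 <- rowSums((X - proj)^2)

  best <- rep(NA_integer_, n)
  best_d2 <- rep(Inf, n)
  o <- order(pid, d2)
  first <- o[!duplicated(pid[o])]
  best[pid[first]] <- first
  list(
    points = proj[best, , drop = FALSE],
    distance = sqrt(d2[best]),
    face = fid[best]
  )
}

# Vectorized exact closest point on triangles (one triangle per row).
# Candidates: the in-plane projection when its barycentric coordinates are
# all nonnegative, the clamped projections onto the three edges, and the
# vertices (covered by edge clamping); the closest valid candidate wins.
point_triangle_closest <- function(X, A, B, C) {
  closest_on_segment <- function(X, S0, S1) {
    d <- S1 - S0
    len2 <- rowSums(d^2)
    t <- rowSums((X - S0) * d) / pmax(len2, 1e-300)
    t <- pmin(pmax(t, 0), 1)
    S0 + d * t
  }
  e1 <- B - A
  e2 <- C - A
  w <- X - A
  d11 <- rowSums(e1 * e1)
  d12 <- rowSums(e1 * e2)
  d22 <- rowSums(e2 * e2)
  w1 <- rowSums(w * e1)
  w2 <- rowSums(w * e2)
  det <- pmax(d11 * d22 - d12^2, 1e-300)
  u <- (d22 * w1 - d12 * w2) / det
  v <- (d11 * w2 - d12 * w1) / det
  inside <- u >= 0 & v >= 0 & (u + v) <= 1
  p_in <- A + e1 * u + e2 * v

  pAB <- closest_on_segment(X, A, B)
  pAC <- closest_on_segment(X, A, C)
  pBC <- closest_on_segment(X, B, C)
  dAB <- rowSums((X - pAB)^2)
  dAC <- rowSums((X - pAC)^2)
  dBC <- rowSums((X - pBC)^2)

  out <- pAB
  sel <- dAC < dAB
  out[sel, ] <- pAC[sel, , drop = FALSE]
  dmin <- pmin(dAB, dAC)
  sel <- dBC < dmin
  out[sel, ] <- pBC[sel, , drop = FALSE]
  out[inside, ] <- p_in[inside, , drop = FALSE]
  out
}
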