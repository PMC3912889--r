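#' Select three spread-out high-curvature reference points
#'
#' From a feature set, picks three spread-out high-curvature landmarks:
#' eligible points are the local curvature maxima of the feature cloud
#' (each maximal within `local_max_radius`), intersected with the top
#' decile by curvature when that leaves enough points; among the
#' eligible points the triple maximizing the minimum pairwise distance
#' wins (so the landmark triangle is as spread out as possible). With at
#' most `exhaustive_limit` eligible points every triple is scored;
#' beyond that a farthest-point heuristic seeds the triple and is
#' refined by coordinate-wise exhaustive swaps.
#'
#' Local maxima (e.g. cusp apices) make robust landmarks across mesh
#' resolutions: a peak of the curvature field stays a feature and stays
#' in place when the surface is resampled, whereas the curvature rank of
#' points on a feature region's rim is sampling-dependent.
#'
#' @param features A `feature_set` from [extract_features()].
#' @param top_fraction Fraction of highest-curvature feature points
#'   eligible (default `0.1`).
#' @param min_eligible Lower bound on the eligible pool (default 12):
#'   on sparse feature sets a strict decile leaves too few points to
#'   form a well-spread, non-degenerate landmark triangle.
#' @param exhaustive_limit Eligible-point count up to which all triples
#'   are enumerated (default 50).
#' @param local_max_radius Radius (mm) within which an eligible point
#'   must have the highest curvature; `NULL` (default) uses 10% of the
#'   feature cloud's bounding-box diagonal; `0` disables the
#'   local-maximum restriction.
#' @return Integer vector of three vertex indices (into the mesh) from
#'   the eligible subset.
#' @export
select_reference_points <- function(features, top_fraction = 0.1,
                                    min_eligible = 12,
                                    exhaustive_limit = 50,
                                    local_max_radius = NULL) {
  stopifnot(inherits(features, "feature_set"))
  tab <- features$table
  n <- nrow(tab)
  if (n < 3) {
    stop_dentalign("dentalign_error_nomatch",
                   sprintf("need at least 3 feature points, have %d", n))
  }
  pts_all <- as.matrix(tab[, c("x", "y", "z")])
  if (is.null(local_max_radius)) {
    rng <- apply(pts_all, 2, range)
    local_max_radius <- 0.1 * sqrt(sum((rng[2, ] - rng[1, ])^2))
  }
  is_max <- rep(TRUE, n)
  if (local_max_radius > 0 && n > 1) {
    kq <- min(n, 32)
    nn <- RANN::nn2(pts_all, pts_all, k = kq)
    for (i in seq_len(n)) {
      nb <- nn$nn.idx[i, nn$nn.dists[i, ] <= local_max_radius]
      is_max[i] <- all(tab$curvature[i] >= tab$curvature[nb])
    }
  }
  pool <- if (sum(is_max) >= 3) which(is_max) else seq_len(n)
  n_top <- max(3L, min_eligible, ceiling(top_fraction * n))
  if (length(pool) > n_top) {
    pool <- pool[order(tab$curvature[pool],
                       decreasing = TRUE)[seq_len(n_top)]]
  }
  elig <- tab[sort(pool), ]
  pts <- as.matrix(elig[, c("x", "y", "z")])
  m <- nrow(pts)

  best <- NULL
  best_val <- -Inf
  if (m <= exhaustive_limit) {
    combs <- utils::combn(m, 3)
    for (k in seq_len(ncol(combs))) {
      i <- combs[, k]
      d <- c(sqrt(sum((pts[i[1], ] - pts[i[2], ])^2)),
             sqrt(sum((pts[i[1], ] - pts[i[3], ])^2)),
             sqrt(sum((pts[i[2], ] - pts[i[3], ])^2)))
      val <- min(d)
      if (val > best_val && !is_collinear(pts[i[1], ], pts[i[2], ], pts[i[3], ])) {
        best_val <- val
        best <- i
      }
    }
  } else {
    # farthest-point seed
    dall <- as.matrix(stats::dist(pts))
    i1 <- which.max(apply(dall, 1, max))
    i2 <- which.max(dall[i1, ])
    i3 <- which.max(pmin(dall[i1, ], dall[i2, ]))
    cur <- c(i1, i2, i3)
    # refine: exhaustively swap one member at a time until stable
    minpair <- function(tr) min(dall[tr[1], tr[2]], dall[tr[1], tr[3]],
                                dall[tr[2], tr[3]])
    repeat {
      improved <- FALSE
      for (slot in 1:3) {
        for (cand in seq_len(m)) {
          tr <- cur
          tr[slot] <- cand
          if (anyDuplicated(tr)) next
          if (minpair(tr) > minpair(cur) &&
              !is_collinear(pts[tr[1], ], pts[tr[2], ], pts[tr[3], ])) {
            cur <- tr
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    if (!is_collinear(pts[cur[1], ], pts[cur[2], ], pts[cur[3], ])) {
      best <- cur
      best_val <- minpair(cur)
    }
  }
  if (is.null(best)) {
    stop_dentalign("dentalign_error_nomatch",
                   "all candidate landmark triples are collinear")
  }
  elig$vertex[best]
}

# Collinearity guard: cross-product norm below 1e-9 times the edge-length
# product.
is_collinear <- function(p1, p2, p3) {
  u <- p3 - p1
  v <- p2 - p1
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(u^2)) * sqrt(sum(v^2))
}

#' Side lengths of a landmark triangle
#'
#' Euclidean distances `(a, b, c) = (|p1 p2|, |p1 p3|, |p2 p3|)` in mm.
#'
#' @param p1,p2,p3 Length-3 points.
#' @return Numeric `c(a, b, c)`.
#' @export
triangle_sides <- function(p1, p2, p3) {
  c(sqrt(sum((p1 - p2)^2)),
    sqrt(sum((p1 - p3)^2)),
    sqrt(sum((p2 - p3)^2)))
}

#' Triangle area from side lengths (Heron's formula)
#'
#' `S = sqrt(s (s - a) (s - b) (s - c))` with `s = (a + b + c) / 2`.
#' Degenerate (collinear) side triples give 0; side triples violating the
#' triangle inequality beyond `tol` raise an error.
#'
#' @param a,b,c Side lengths (mm), nonnegative.
#' @param tol Relative tolerance on triangle-inequality violations
#'   (default `1e-9`).
#' @return Area in mm^2.
#' @export
triangle_area <- function(a, b, c, tol = 1e-9) {
  stopifnot(a >= 0, b >= 0, c >= 0)
  s <- (a + b + c) / 2
  terms <- c(s, s - a, s - b, s - c)
  scale <- max(a, b, c, 1e-300)
  if (any(terms < -tol * scale)) {
    stop_dentalign("dentalign_error_geometry",
                   sprintf("side lengths (%g, %g, %g) violate the triangle inequality",
                           a, b, c))
  }
  sqrt(prod(pmax(terms, 0)))
}

#' Curvature-similar candidate correspondences
#'
#' For one reference feature point, lists the target feature vertices
#' whose curvature is similar to the reference point's, sorted by
#' ascending deviation and capped at `max_candidates` (so the downstream
#' triple search stays bounded).
#'
#' With `metric = "absolute"` (the default) similarity is the absolute
#' curvature difference in mm^-2, suited to model pairs of comparable
#' resolution. Discrete angle-deficit curvature depends on triangle
#' size, so for meshes of very different resolution the raw values are
#' not commensurable; `metric = "quantile"` instead compares the
#' curvature's rank within each mesh's own feature set (empirical
#' quantile in `[0, 1]`), which is robust to the resolution-induced
#' rescaling. In that mode `ref_curvature` must already be the
#' landmark's curvature quantile within the reference feature set, and
#' `curv_tol` is on the quantile scale.
#'
#' @param ref_curvature Curvature of the reference point (mm^-2), or its
#'   quantile within the reference feature set when
#'   `metric = "quantile"`.
#' @param target_features A `feature_set` for the target mesh.
#' @param curv_tol Curvature-similarity threshold, `> 0`: mm^-2 for
#'   `"absolute"` (default `0.00015`), quantile points for
#'   `"quantile"`.
#' @param max_candidates Cap on the returned list (default 64).
#' @param metric `"absolute"` (default) or `"quantile"`.
#' @return A tibble: `vertex`, `x`, `y`, `z`, `curvature`, `deviation`,
#'   sorted by `deviation`.
#' @export
candidate_correspondences <- function(ref_curvature, target_features,
                                      curv_tol = 0.00015,
                                      max_candidates = 64,
                                      metric = c("absolute", "quantile")) {
  metric <- match.arg(metric)
  stopifnot(inherits(target_features, "feature_set"), curv_tol > 0)
  tab <- target_features$table
  val <- if (metric == "quantile") {
    stats::ecdf(tab$curvature)(tab$curvature)
  } else {
    tab$curvature
  }
  dev <- abs(val - ref_curvature)
  keep <- which(dev < curv_tol)
  keep <- keep[order(dev[keep])]
  keep <- utils::head(keep, max_candidates)
  out <- tab[keep, ]
  out$deviation <- dev[keep]
  out
}

#' Match a landmark triple under distance and area constraints
#'
#' Given three reference landmark points (with curvatures) and the target
#' feature set, finds the target triple `(n1, n2, n3)` — one vertex from
#' each point's curvature-similar candidate list — satisfying the rigid
#' invariance constraints: every side-length deviation
#' `|d_mi_mj - d_ni_nj| < dist_tol` and the Heron-area deviation
#' `|S(m) - S(n)| < area_tol`. Distances and areas are preserved by rigid
#' motion, so the true correspondence always satisfies them regardless of
#' pose. Among satisfying triples the one minimizing the combined
#' normalized residual `sum(side deviations) / dist_tol +
#' area deviation / area_tol` is returned.
#'
#' Congruence alone can be ambiguous: regular meshes contain many
#' near-congruent triples, so the lowest-residual survivor is not always
#' the true correspondence. When `ref_features` is supplied, the
#' `verify_n` best-scoring survivors are verified by alignment: each
#' candidate triple defines a coarse transform ([coarse_transform()]),
#' the reference feature points are mapped through it, and the triple
#' whose transform gives the smallest mean nearest-neighbour distance to
#' the target features wins. This keeps the selection among constrained
#' triples but breaks score ties by the quantity registration actually
#' cares about.
#'
#' @param ref_points 3x3 matrix, one reference landmark per row (mm).
#' @param ref_curvatures Length-3 curvatures of the landmarks (mm^-2).
#' @param target_features A `feature_set` for the target mesh.
#' @param curv_tol Curvature-similarity gate, see
#'   [candidate_correspondences()].
#' @param dist_tol Side-length deviation threshold (mm), default 1.
#' @param area_tol Area deviation threshold (mm^2), default 1.
#' @param max_candidates Candidate-list cap per landmark (default 64).
#' @param metric Curvature-similarity metric, see
#'   [candidate_correspondences()]; with `"quantile"`,
#'   `ref_curvatures` must be the landmarks' curvature quantiles within
#'   the reference feature set.
#' @param ref_features Optional `feature_set` (or n x 3 matrix) of all
#'   reference feature points, enabling alignment verification of the
#'   best-scoring survivors.
#' @param verify_n Number of top-scoring survivors to verify (default
#'   `Inf`: all retained survivors).
#' @param n_hypotheses Number of rotation-diverse top-verified poses to
#'   report (default 1). With more than one, the `hypotheses` field
#'   lists runner-up triples whose poses differ by over 20 degrees, so
#'   a caller can re-check near-ties after refinement.
#' @return An object of class `correspondence_triple`: list with
#'   `target_vertices` (length-3 vertex indices), `target_points` (3x3),
#'   `curvature_deviations`, `side_deviations` (mm), `area_deviation`
#'   (mm^2), `score`, `n_survivors`, `verified_distance` (mm, when
#'   verification ran) and `hypotheses` (see `n_hypotheses`).
#' @export
match_triple <- function(ref_points, ref_curvatures, target_features,
                         curv_tol = 0.00015, dist_tol = 1.0, area_tol = 1.0,
                         max_candidates = 64,
                         metric = c("absolute", "quantile"),
                         ref_features = NULL, verify_n = Inf,
                         n_hypotheses = 1) {
  metric <- match.arg(metric)
  hypotheses <- NULL
  ref_points <- as.matrix(ref_points)
  stopifnot(all(dim(ref_points) == c(3, 3)), length(ref_curvatures) == 3,
            dist_tol > 0, area_tol > 0)
  cand <- lapply(1:3, function(i) {
    candidate_correspondences(ref_curvatures[i], target_features,
                              curv_tol = curv_tol,
                              max_candidates = max_candidates,
                              metric = metric)
  })
  n_cand <- vapply(cand, nrow, 1L)
  if (any(n_cand == 0)) {
    stop_dentalign(
      "dentalign_error_nomatch",
      sprintf("no curvature-similar candidates for reference point(s) %s (curv_tol = %g)",
              paste(which(n_cand == 0), collapse = ", "), curv_tol)
    )
  }
  d_ref <- triangle_sides(ref_points[1, ], ref_points[2, ], ref_points[3, ])
  s_ref <- triangle_area(d_ref[1], d_ref[2], d_ref[3])

  P1 <- as.matrix(cand[[1]][, c("x", "y", "z")])
  P2 <- as.matrix(cand[[2]][, c("x", "y", "z")])
  P3 <- as.matrix(cand[[3]][, c("x", "y", "z")])

  # pairwise candidate distances, computed once
  cross_dist <- function(A, B) {
    # |A_i - B_j| for all i, j
    sqrt(pmax(outer(rowSums(A^2), rep(1, nrow(B))) +
                outer(rep(1, nrow(A)), rowSums(B^2)) -
                2 * A %*% t(B), 0))
  }
  D12 <- cross_dist(P1, P2)
  D13 <- cross_dist(P1, P3)
  D23 <- cross_dist(P2, P3)
  v1 <- cand[[1]]$vertex; v2 <- cand[[2]]$vertex; v3 <- cand[[3]]$vertex

  # enumerate constrained triples: for each n1, intersect the n2 and n3
  # sets passing their side constraints, then test the (n2, n3) side and
  # the area on the small submatrix
  surv <- vector("list", n_cand[1])
  best_seen <- c(Inf, Inf, Inf, Inf)  # best residuals for the error message
  heron <- function(a, b, c) {
    s <- (a + b + c) / 2
    sqrt(pmax(s * (s - a) * (s - b) * (s - c), 0))
  }
  for (i1 in seq_len(n_cand[1])) {
    dev12 <- abs(D12[i1, ] - d_ref[1])
    dev13 <- abs(D13[i1, ] - d_ref[2])
    A <- which(dev12 < dist_tol & v2 != v1[i1])
    B <- which(dev13 < dist_tol & v3 != v1[i1])
    if (length(A) == 0 || length(B) == 0) {
      j2 <- which.min(dev12); j3 <- which.min(dev13)
      cand_res <- c(dev12[j2], dev13[j3], Inf, Inf)
      if (sum(cand_res[1:2]) < sum(best_seen[1:2])) best_seen <- cand_res
      next
    }
    sub <- D23[A, B, drop = FALSE]
    dev23 <- abs(sub - d_ref[3])
    hit <- which(dev23 < dist_tol & outer(v2[A], v3[B], "!="), arr.ind = TRUE)
    if (nrow(hit) == 0) {
      j <- arrayInd(which.min(dev23), dim(dev23))
      cand_res <- c(dev12[A[j[1]]], dev13[B[j[2]]], min(dev23), Inf)
      if (sum(cand_res[1:3]) < sum(best_seen[1:3])) best_seen <- cand_res
      next
    }
    i2 <- A[hit[, 1]]
    i3 <- B[hit[, 2]]
    s_tgt <- heron(D12[cbind(i1, i2)], D13[cbind(i1, i3)],
                   D23[cbind(i2, i3)])
    dev_s <- abs(s_tgt - s_ref)
    jj <- which.min(dev12[i2] + dev13[i3] + dev23[hit])
    cand_res <- c(dev12[i2[jj]], dev13[i3[jj]], dev23[hit][jj], dev_s[jj])
    if (sum(cand_res[1:3]) < sum(best_seen[1:3])) best_seen <- cand_res
    pass <- dev_s < area_tol
    if (!any(pass)) next
    surv[[i1]] <- cbind(
      i1 = i1, i2 = i2[pass], i3 = i3[pass],
      dev12 = dev12[i2[pass]], dev13 = dev13[i3[pass]],
      dev23 = dev23[hit][pass], dev_s = dev_s[pass],
      score = (dev12[i2[pass]] + dev13[i3[pass]] + dev23[hit][pass]) /
        dist_tol + dev_s[pass] / area_tol
    )
  }
  surv <- do.call(rbind, surv)
  if (is.null(surv) || nrow(surv) == 0) {
    stop_dentalign(
      "dentalign_error_nomatch",
      sprintf(paste0("no candidate triple satisfies the constraints ",
                     "(best side deviations %.4g/%.4g/%.4g mm, area deviation %.4g mm^2; ",
                     "dist_tol = %g, area_tol = %g)"),
              best_seen[1], best_seen[2], best_seen[3], best_seen[4],
              dist_tol, area_tol)
    )
  }
  surv <- surv[order(surv[, "score"]), , drop = FALSE]
  n_surv <- nrow(surv)
  if (n_surv > 200000) surv <- surv[seq_len(200000), , drop = FALSE]

  pick <- 1L
  verified_distance <- NA_real_
  if (!is.null(ref_features)) {
    refp <- if (inherits(ref_features, "feature_set")) {
      feature_points(ref_features)
    } else {
      as.matrix(ref_features)
    }
    n_try <- as.integer(min(verify_n, nrow(surv)))
    vp <- triple_poses(ref_points,
                       P1[surv[seq_len(n_try), "i1"], , drop = FALSE],
                       P2[surv[seq_len(n_try), "i2"], , drop = FALSE],
                       P3[surv[seq_len(n_try), "i3"], , drop = FALSE])
    valid <- which(vp$ok)
    # survivors sharing (almost) one pose are redundant: keep the
    # best-scoring representative per quantized pose
    key <- do.call(paste, c(
      lapply(1:6, function(j) round(vp$R9[valid, j] / 0.05)),
      lapply(1:3, function(j) round(vp$Tt[valid, j] / 0.5))
    ))
    reps <- valid[!duplicated(key)]
    nr <- nrow(refp)
    # mapped reference features for every distinct pose, fully batched:
    # three matmuls give all x, y, z coordinates at once
    RX <- refp %*% t(vp$R9[reps, 1:3, drop = FALSE]) # nr x nreps
    RY <- refp %*% t(vp$R9[reps, 4:6, drop = FALSE])
    RZ <- refp %*% t(vp$R9[reps, 7:9, drop = FALSE])
    moved_all <- cbind(
      as.vector(RX) + rep(vp$Tt[reps, 1], each = nr),
      as.vector(RY) + rep(vp$Tt[reps, 2], each = nr),
      as.vector(RZ) + rep(vp$Tt[reps, 3], each = nr)
    )
    # verification: root-mean-square distance of the mapped reference
    # features to the target. A cheap nearest-feature pass ranks all
    # distinct poses; the best are then re-scored against the target
    # surface itself (features of a coarser mesh sit ON the denser
    # surface under the true pose, which separates symmetry flips)
    tgtp <- feature_points(target_features)
    d_feat <- RANN::nn2(tgtp, moved_all, k = 1)$nn.dists[, 1]
    rms_feat <- sqrt(colMeans(matrix(d_feat^2, nrow = nr)))
    if (!is.null(target_features$mesh)) {
      top <- order(rms_feat)[seq_len(min(4000L, length(reps)))]
      sel <- rep((top - 1) * nr, each = nr) + seq_len(nr)
      d_surf <- closest_point_on_mesh(target_features$mesh,
                                      moved_all[sel, , drop = FALSE])$distance
      rms_surf <- sqrt(colMeans(matrix(d_surf^2, nrow = nr)))
      o <- order(rms_surf)
      pick <- reps[top[o[1]]]
      verified_distance <- rms_surf[o[1]]
      if (n_hypotheses > 1) {
        # rotation-diverse runners-up: poses at least 20 degrees from
        # every already-chosen one
        chosen <- top[o[1]]
        chosen_rms <- rms_surf[o[1]]
        for (j in o[-1]) {
          if (length(chosen) >= n_hypotheses) break
          cand_r <- top[j]
          angs <- vapply(chosen, function(cr) {
            Ra <- matrix(vp$R9[reps[cr], ], 3, 3, byrow = TRUE)
            Rb <- matrix(vp$R9[reps[cand_r], ], 3, 3, byrow = TRUE)
            rotation_angle(crossprod(Ra, Rb))
          }, numeric(1))
          if (all(angs > 20 * pi / 180)) {
            chosen <- c(chosen, cand_r)
            chosen_rms <- c(chosen_rms, rms_surf[j])
          }
        }
        hypotheses <- lapply(seq_along(chosen), function(h) {
          r <- reps[chosen[h]]
          b <- surv[r, ]
          list(
            target_vertices = c(cand[[1]]$vertex[b["i1"]],
                                cand[[2]]$vertex[b["i2"]],
                                cand[[3]]$vertex[b["i3"]]),
            target_points = rbind(P1[b["i1"], ], P2[b["i2"], ],
                                  P3[b["i3"], ]),
            pose = rigid_transform(matrix(vp$R9[r, ], 3, 3, byrow = TRUE),
                                   vp$Tt[r, ], tol = 1e-6),
            verified_distance = chosen_rms[h]
          )
        })
      }
    } else {
      pick <- reps[which.min(rms_feat)]
      verified_distance <- min(rms_feat)
    }
  }

  b <- surv[pick, ]
  structure(
    list(
      target_vertices = c(cand[[1]]$vertex[b["i1"]],
                          cand[[2]]$vertex[b["i2"]],
                          cand[[3]]$vertex[b["i3"]]),
      target_points = rbind(P1[b["i1"], ], P2[b["i2"], ], P3[b["i3"], ]),
      curvature_deviations = c(cand[[1]]$deviation[b["i1"]],
                               cand[[2]]$deviation[b["i2"]],
                               cand[[3]]$deviation[b["i3"]]),
      side_deviations = unname(b[c("dev12", "dev13", "dev23")]),
      area_deviation = unname(b["dev_s"]),
      score = unname(b["score"]),
      n_survivors = n_surv,
      verified_distance = verified_distance,
      hypotheses = hypotheses
    ),
    class = "correspondence_triple"
  )
}

# Batched coarse poses: the rigid transform of coarse_transform() for many
# candidate target triples at once. Returns the rotation rows flattened
# (R9: columns 1:3 = first row of R, etc.), translations, and a validity
# flag (FALSE for collinear/degenerate triples).
triple_poses <- function(m_triple, N1, N2, N3) {
  Tm <- local_frame(m_triple[1, ], m_triple[2, ], m_triple[3, ])
  cm <- colMeans(m_triple)
  u <- N3 - N1
  v <- N2 - N1
  nu <- sqrt(rowSums(u^2))
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  ncr <- sqrt(rowSums(cr^2))
  ok <- nu > 0 & ncr > 1e-9 * nu * sqrt(rowSums(v^2))
  t1 <- u / pmax(nu, 1e-300)
  t2 <- cr / pmax(ncr, 1e-300)
  t3 <- cbind(t1[, 2] * t2[, 3] - t1[, 3] * t2[, 2],
              t1[, 3] * t2[, 1] - t1[, 1] * t2[, 3],
              t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1])
  # R = Tn Tm', so R[i, j] = sum_k Tn[i, k] Tm[j, k]
  R9 <- matrix(0, nrow(N1), 9)
  for (i in 1:3) {
    for (j in 1:3) {
      R9[, (i - 1) * 3 + j] <- t1[, i] * Tm[j, 1] + t2[, i] * Tm[j, 2] +
        t3[, i] * Tm[j, 3]
    }
  }
  cn <- (N1 + N2 + N3) / 3
  Tt <- cbind(
    cn[, 1] - (R9[, 1] * cm[1] + R9[, 2] * cm[2] + R9[, 3] * cm[3]),
    cn[, 2] - (R9[, 4] * cm[1] + R9[, 5] * cm[2] + R9[, 6] * cm[3]),
    cn[, 3] - (R9[, 7] * cm[1] + R9[, 8] * cm[2] + R9[, 9] * cm[3])
  )
  list(R9 = R9, Tt = Tt, ok = ok)
}

#' @export
print.correspondence_triple <- function(x, ...) {
  cat("<correspondence_triple>\n")
  cat("  target vertices:", paste(x$target_vertices, collapse = ", "), "\n")
  cat(sprintf("  side deviations (mm): %.4g %.4g %.4g\n",
              x$side_deviations[1], x$side_deviations[2],
              x$side_deviations[3]))
  cat(sprintf("  area deviation (mm^2): %.4g\n", x$area_deviation))
  invisible(x)
}

#' Orthonormal local frame of a landmark triple
#'
#' Builds the frame `(t1, t2, t3)` (columns): `t1` along `p3 - p1`
#' normalized, `t2` along `(p3 - p1) x (p2 - p1)` normalized, and
#' `t3 = t1 x t2`.
#'
#' @param p1,p2,p3 Length-3 points (not collinear).
#' @return 3x3 matrix with orthonormal columns `t1`, `t2`, `t3`.
#' @export
local_frame <- function(p1, p2, p3) {
  if (is_collinear(p1, p2, p3)) {
    stop_dentalign("dentalign_error_geometry",
                   "landmark points are collinear; local frame undefined")
  }
  u <- p3 - p1
  v <- p2 - p1
  t1 <- u / sqrt(sum(u^2))
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  t2 <- cr / sqrt(sum(cr^2))
  t3 <- c(t1[2] * t2[3] - t1[3] * t2[2],
          t1[3] * t2[1] - t1[1] * t2[3],
          t1[1] * t2[2] - t1[2] * t2[1])
  cbind(t1, t2, t3, deparse.level = 0)
}

#' Coarse rigid transform from two matched landmark triples
#'
#' From the reference triple `m` and its matched target triple `n`,
#' builds the local frames `Tm`, `Tn` ([local_frame()]) and returns the
#' frame-to-frame rotation `R = Tn Tm'` with translation
#' `T = centroid(n) - R centroid(m)`, i.e. the rigid transform carrying
#' the `m` triple onto the `n` triple.
#'
#' @param m_triple,n_triple 3x3 matrices, one landmark per row.
#' @return A [rigid_transform()] mapping m-frame points to n-frame
#'   points.
#' @export
coarse_transform <- function(m_triple, n_triple) {
  m_triple <- as.matrix(m_triple)
  n_triple <- as.matrix(n_triple)
  stopifnot(all(dim(m_triple) == c(3, 3)), all(dim(n_triple) == c(3, 3)))
  Tm <- local_frame(m_triple[1, ], m_triple[2, ], m_triple[3, ])
  Tn <- local_frame(n_triple[1, ], n_triple[2, ], n_triple[3, ])
  R <- Tn %*% t(Tm)
  Tt <- colMeans(n_triple) - as.numeric(R %*% colMeans(m_triple))
  rigid_transform(R, Tt, tol = 1e-6)
}
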