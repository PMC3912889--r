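# shared fixtures and oracles, all generated in code

# a same-resolution pair: full phantom vs an exactly rigidly displaced copy
make_exact_pair <- function(seed, rotation_max = 30, translation_max = 20) {
  make_pair(make_phantom(seed = seed), rotation_max = rotation_max,
            translation_max = translation_max, crop_fraction = 1,
            decimate_keep_fraction = 1, noise_sd = 0, seed = seed)
}

# the cross-resolution registration configuration exercised in the
# phantom study (quantile curvature matching, wide rigid-invariant gates,
# surface refinement)
study_config <- list(
  curv_tol = 0.3, curv_metric = "quantile", max_candidates = 192,
  dist_tol = 2.5, area_tol = 10, refine_full = TRUE
)

register_study <- function(pair) {
  register_meshes(pair$reference, pair$target,
                  curv_tol = study_config$curv_tol,
                  curv_metric = study_config$curv_metric,
                  max_candidates = study_config$max_candidates,
                  dist_tol = study_config$dist_tol,
                  area_tol = study_config$area_tol,
                  refine_full = study_config$refine_full)
}

rotation_error_deg <- function(R_est, R_true) {
  rotation_angle(crossprod(as.matrix(R_est), as.matrix(R_true))) * 180 / pi
}

translation_error_mm <- function(t_est, t_true) {
  sqrt(sum((t_est$T - t_true$T)^2))
}

random_points <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 10), ncol = 3)
}

# exhaustive oracle for the greedy unique assignment: all pairs in
# ascending distance (ties: lower reference index, then lower query
# index), assigned greedily
greedy_unique_oracle <- function(Q, P) {
  np <- nrow(P); nq <- nrow(Q)
  g <- expand.grid(p = seq_len(np), q = seq_len(nq))
  d <- sqrt(rowSums((P[g$p, , drop = FALSE] - Q[g$q, , drop = FALSE])^2))
  ord <- order(d, g$q, g$p)
  assigned <- rep(NA_integer_, np)
  claimed <- rep(FALSE, nq)
  for (k in ord) {
    p <- g$p[k]; q <- g$q[k]
    if (is.na(assigned[p]) && !claimed[q]) {
      assigned[p] <- q
      claimed[q] <- TRUE
    }
  }
  assigned
}

# a published five-decimal rotation matrix used as a validator fixture
printed_rotation <- rbind(
  c(-0.82982, 0.24221, -0.50271),
  c(-0.33881, -0.93451, 0.10903),
  c(-0.44338, 0.26080, 0.85755)
)

# minimal binary STL written byte by byte (one unit triangle)
write_minimal_binary_stl <- function(path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(c(0, 0, 1,  0, 0, 0,  1, 0, 0,  0, 1, 0), con, size = 4,
           endian = "little")
  writeBin(0L, con, size = 2, endian = "little")
  invisible(path)
}

write_minimal_ascii_stl <- function(path) {
  writeLines(c(
    "solid tri",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid tri"
  ), path)
  invisible(path)
}

# a synthetic feature set from bare points + curvatures (no mesh)
fake_feature_set <- function(pts, curv, alpha = 0.01) {
  structure(
    list(
      table = tibble::tibble(
        vertex = seq_len(nrow(pts)),
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        curvature = curv
      ),
      alpha = alpha, signed = FALSE, mesh = NULL
    ),
    class = "feature_set"
  )
}
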