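test_that("triangle sides follow the (p1p2, p1p3, p2p3) order", {
  expect_equal(triangle_sides(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
               c(3, 4, 5))
  expect_equal(triangle_sides(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
               c(0, 0, 0))
  set.seed(9)
  p <- lapply(1:3, function(i) rnorm(3))
  expect_equal(triangle_sides(p[[1]], p[[2]], p[[3]]),
               c(sqrt(sum((p[[1]] - p[[2]])^2)),
                 sqrt(sum((p[[1]] - p[[3]])^2)),
                 sqrt(sum((p[[2]] - p[[3]])^2))))
})

test_that("Heron's formula gives textbook areas and flags impossible sides", {
  expect_equal(triangle_area(2, 2, 2), sqrt(3), tolerance = 1e-12)
  expect_equal(triangle_area(3, 4, 5), 6, tolerance = 1e-12)
  expect_equal(triangle_area(1, 2, 3), 0)  # collinear
  expect_error(triangle_area(1, 1, 5), class = "dentalign_error_geometry")
})

test_that("landmark selection spreads the triple over well-separated groups", {
  # 30 points in 3 well-separated clusters: the max-min-distance triple
  # takes one point per cluster (brute-force oracle over all C(30,3))
  set.seed(21)
  centers <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0))
  pts <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(30, sd = 1), ncol = 3), 2, centers[k, ], "+")
  }))
  curv <- runif(30, 0.5, 1)
  fs <- fake_feature_set(pts, curv)
  sel <- select_reference_points(fs, top_fraction = 1, min_eligible = 30,
                                 local_max_radius = 0)
  combs <- utils::combn(30, 3)
  minpair <- apply(combs, 2, function(i) {
    min(dist(pts[i, ]))
  })
  oracle <- combs[, which.max(minpair)]
  expect_setequal(sel, oracle)
  expect_equal(sort(ceiling(sel / 10)), 1:3)  # one per cluster

  # by default, eligible points are the local curvature maxima: the
  # selected landmarks are then each cluster's curvature peak
  sel_max <- select_reference_points(fs)
  peaks <- sapply(0:2, function(k) 10 * k + which.max(curv[10 * k + 1:10]))
  expect_setequal(sel_max, peaks)
})

test_that("landmark selection needs three non-collinear feature points", {
  pts3 <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  fs3 <- fake_feature_set(pts3, c(1, 2, 3))
  expect_setequal(select_reference_points(fs3), 1:3)

  fs2 <- fake_feature_set(pts3[1:2, ], c(1, 2))
  expect_error(select_reference_points(fs2),
               class = "dentalign_error_nomatch")

  line <- cbind(seq(0, 10, length.out = 5), 0, 0)
  fsl <- fake_feature_set(line, rep(1, 5))
  expect_error(select_reference_points(fsl, local_max_radius = 0),
               class = "dentalign_error_nomatch")
})

test_that("candidate lists keep curvature-similar points only, ranked by deviation", {
  pts <- matrix(rnorm(60), ncol = 3)
  curv <- c(0.100, 0.1001, 0.1004, 0.100299, rep(0.2, 16))
  fs <- fake_feature_set(pts, curv)
  cand <- candidate_correspondences(0.1, fs, curv_tol = 0.00035)
  expect_equal(cand$vertex, c(1L, 2L, 4L))
  expect_false(is.unsorted(cand$deviation))
  # decoys at twice the tolerance are excluded (brute-force filter oracle)
  expect_true(all(abs(curv[cand$vertex] - 0.1) < 0.00035))
  expect_equal(nrow(candidate_correspondences(0.5, fs, curv_tol = 0.00015)), 0)
  # cap limits the list
  expect_equal(nrow(candidate_correspondences(0.2, fs, curv_tol = 1,
                                              max_candidates = 5)), 5)
})

test_that("match_triple recovers the planted triple on a rigid copy", {
  pair <- make_exact_pair(seed = 31)
  fr <- extract_features(pair$reference, 0.01)
  ft <- extract_features(pair$target, 0.01)
  lm <- select_reference_points(fr)
  rows <- match(lm, fr$table$vertex)
  m_pts <- as.matrix(fr$table[rows, c("x", "y", "z")])
  trip <- match_triple(m_pts, fr$table$curvature[rows], ft,
                       curv_tol = 0.00015, dist_tol = 1, area_tol = 1)
  # exact copy: vertex indexing is preserved, so the planted triple is lm
  expect_equal(trip$target_vertices, lm)
  expect_true(all(trip$side_deviations < 1e-9))
  expect_lt(trip$area_deviation, 1e-9)
})

test_that("match_triple rejects decoys violating the distance constraint", {
  # reference landmarks: a 6-8-10 triangle
  m_pts <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 8, 0))
  m_curv <- c(0.10, 0.20, 0.30)
  # target: the true correspondents plus a curvature-matched decoy for n1
  # displaced so its side lengths are off by 3x the tolerance
  tgt <- rbind(
    c(100, 0, 0), c(106, 0, 0), c(100, 8, 0),   # true triple
    c(103, 0, 0)                                # decoy near n1's curvature
  )
  fs <- fake_feature_set(tgt, c(0.10, 0.20, 0.30, 0.100001))
  trip <- match_triple(m_pts, m_curv, fs, curv_tol = 0.00015,
                       dist_tol = 1, area_tol = 1)
  expect_equal(trip$target_vertices, c(1L, 2L, 3L))

  # with only the decoy available for n1, no triple satisfies the bound
  fs2 <- fake_feature_set(tgt[2:4, ], c(0.20, 0.30, 0.100001))
  expect_error(
    match_triple(m_pts, m_curv, fs2, curv_tol = 0.00015,
                 dist_tol = 1, area_tol = 1),
    class = "dentalign_error_nomatch"
  )

  # empty candidate list for a landmark
  expect_error(
    match_triple(m_pts, c(5, 5, 5), fs, curv_tol = 0.00015,
                 dist_tol = 1, area_tol = 1),
    class = "dentalign_error_nomatch"
  )
})

test_that("local frames are orthonormal and built from the stated axes", {
  fr <- local_frame(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  expect_equal(fr[, 1], c(1, 0, 0))
  expect_equal(fr[, 2], c(0, 0, 1))
  expect_equal(fr[, 3], c(0, -1, 0))

  for (s in 1:20) {
    set.seed(400 + s)
    p <- matrix(rnorm(9, sd = 5), 3)
    if (dentalign:::is_collinear(p[1, ], p[2, ], p[3, ])) next
    f <- local_frame(p[1, ], p[2, ], p[3, ])
    expect_equal(crossprod(f), diag(3), tolerance = 1e-12)
    expect_equal(det(f), 1, tolerance = 1e-12)
  }

  expect_error(local_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "dentalign_error_geometry")
})

test_that("coarse transforms reproduce planted rigid motions from matched triples", {
  m <- rbind(c(0, 0, 0), c(5, 1, 0), c(2, 6, 1))
  ident <- coarse_transform(m, m)
  expect_equal(ident$R, diag(3), tolerance = 1e-12)
  expect_equal(ident$T, c(0, 0, 0), tolerance = 1e-12)

  shift <- coarse_transform(m, m + matrix(c(1, 2, 3), 3, 3, byrow = TRUE))
  expect_equal(shift$R, diag(3), tolerance = 1e-12)
  expect_equal(shift$T, c(1, 2, 3), tolerance = 1e-12)

  Rz <- rotation_about_axis(c(0, 0, 1), pi / 2)
  rot <- coarse_transform(m, m %*% t(Rz))
  expect_equal(rot$R, Rz, tolerance = 1e-12)

  # frame-based and SVD estimates agree on exact rigid triples
  for (s in 1:10) {
    tr <- random_rigid_transform(120, 30, seed = 500 + s)
    n <- transform_points(tr, m)
    ct <- coarse_transform(m, n)
    sv <- estimate_rigid_svd(m, n)
    expect_equal(ct$R, sv$R, tolerance = 1e-9)
    expect_equal(ct$T, sv$T, tolerance = 1e-9)
    expect_lt(max(abs(transform_points(ct, m) - n)), 1e-9)
  }
})

test_that("distance and area constraints are rigid-motion invariant", {
  set.seed(33)
  p <- matrix(rnorm(9, sd = 8), 3)
  s0 <- triangle_sides(p[1, ], p[2, ], p[3, ])
  a0 <- triangle_area(s0[1], s0[2], s0[3])
  for (s in 1:10) {
    tr <- random_rigid_transform(180, 100, seed = 600 + s)
    q <- transform_points(tr, p)
    s1 <- triangle_sides(q[1, ], q[2, ], q[3, ])
    expect_equal(s1, s0, tolerance = 1e-9)
    expect_equal(triangle_area(s1[1], s1[2], s1[3]), a0, tolerance = 1e-9)
  }
})
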