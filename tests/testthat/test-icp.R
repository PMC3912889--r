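test_that("unique assignment matches identical subsets at zero distance", {
  Q <- random_points(20, seed = 41)
  P <- Q[5:10, ]
  m <- nearest_unique(Q, P)
  expect_equal(m$index, 5:10)
  expect_equal(m$distance, rep(0, 6))

  m1 <- nearest_unique(rbind(c(1, 2, 3)), rbind(c(0, 0, 0)))
  expect_equal(m1$index, 1L)
  expect_equal(m1$distance, sqrt(14))

  expect_error(nearest_unique(random_points(3, 1), random_points(4, 2)),
               class = "dentalign_error_geometry")
})

test_that("contended reference points go to the closer query point", {
  Q <- rbind(c(0, 0, 0), c(10, 0, 0))
  P <- rbind(c(0.1, 0, 0), c(0.2, 0, 0))   # both nearest to Q1
  m <- nearest_unique(Q, P)
  expect_equal(m$index, c(1L, 2L))          # P1 is closer, keeps Q1
  expect_equal(m$distance, c(0.1, 9.8))
})

test_that("unique assignment agrees with the exhaustive greedy oracle", {
  for (s in 1:150) {
    set.seed(700 + s)
    np <- sample(1:8, 1)
    nq <- if (np == 8) 8L else sample(seq(np, 8), 1)
    P <- matrix(rnorm(3 * np), ncol = 3)
    Q <- matrix(rnorm(3 * nq), ncol = 3)
    expect_equal(nearest_unique(Q, P)$index, greedy_unique_oracle(Q, P),
                 info = sprintf("instance %d", s))
  }
})

test_that("the mean residual is the average unsquared distance", {
  P <- random_points(8, seed = 43)
  expect_equal(mean_residual(P, P), 0)
  expect_equal(mean_residual(rbind(c(0, 0, 0), c(0, 0, 0)),
                             rbind(c(1, 0, 0), c(3, 0, 0))), 2)
  D <- P + matrix(rnorm(24), ncol = 3)
  expect_equal(mean_residual(P, D),
               mean(sqrt(rowSums((P - D)^2))))
  expect_error(mean_residual(P, D[1:3, ]), class = "dentalign_error_geometry")
})

test_that("identical point sets converge at the first comparison", {
  P <- random_points(25, seed = 44)
  res <- icp_register(P, P)
  expect_true(res$converged)
  expect_equal(res$iterations, 2L)
  expect_lt(max(res$residuals), 1e-12)
  expect_length(res$residuals, res$iterations + 1)
  expect_equal(res$transform$R, diag(3), tolerance = 1e-12)
  expect_equal(res$transform$T, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(res$stop_reason, "tolerance")
})

test_that("an infinite tolerance stops at the first residual comparison", {
  P <- random_points(10, seed = 45)
  Q <- random_points(30, seed = 46)
  init <- random_rigid_transform(20, 5, seed = 47)
  res <- icp_register(P, Q, init = init, mu = Inf)
  expect_true(res$converged)
  # init application, one estimated update, then the (vacuous) comparison
  expect_equal(res$iterations, 2L)
  expect_length(res$residuals, 3)
})

test_that("the squared objective is non-increasing with classic assignment", {
  pair <- make_exact_pair(seed = 48, rotation_max = 10, translation_max = 3)
  P <- pair$target$vertices
  Q <- pair$reference$vertices
  res <- icp_register(P, Q, assignment = "closest", mu = 1e-9,
                      max_iter = 60)
  expect_true(all(diff(res$objective) <= 1e-12))
  expect_length(res$residuals, res$iterations + 1)
  expect_length(res$objective, res$iterations + 1)
})

test_that("registration is equivariant under a rigid motion of the reference", {
  pair <- make_exact_pair(seed = 49, rotation_max = 10, translation_max = 3)
  fs_p <- extract_features(pair$target, 0.01)
  fs_q <- extract_features(pair$reference, 0.01)
  P <- dentalign:::feature_points(fs_p)
  Q <- dentalign:::feature_points(fs_q)
  P <- P[seq_len(min(nrow(P), nrow(Q))), , drop = FALSE]
  init <- pair$ground_truth
  res1 <- icp_register(P, Q, init = init, mu = 1e-9)

  G <- random_rigid_transform(40, 15, seed = 50)
  res2 <- icp_register(P, transform_points(G, Q),
                       init = compose_transforms(G, init), mu = 1e-9)
  expected <- compose_transforms(G, res1$transform)
  expect_equal(res2$transform$R, expected$R, tolerance = 1e-6)
  expect_equal(res2$transform$T, expected$T, tolerance = 1e-6)
})

test_that("ICP recovers the displacement of an exact full copy from identity", {
  pair <- make_exact_pair(seed = 51, rotation_max = 10, translation_max = 5)
  res <- icp_register(pair$target$vertices, pair$reference$vertices,
                      mu = 1e-9, max_iter = 200)
  gt <- pair$ground_truth
  expect_lt(res$residuals[length(res$residuals)], 1e-9)
  expect_lt(rotation_error_deg(res$transform$R, gt$R), 1e-6)
  expect_lt(translation_error_mm(res$transform, gt), 1e-6)
})

test_that("refinement never ends worse than its starting transform", {
  for (s in 1:20) {
    ph <- make_phantom(grid_res = 32, seed = 900 + s)
    pair <- make_pair(ph, rotation_max = 10, translation_max = 3,
                      seed = 900 + s)
    fs_q <- extract_features(pair$reference, 0.01)
    Q <- dentalign:::feature_points(fs_q)
    fs_p <- extract_features(pair$target, 0.01)
    P <- dentalign:::feature_points(fs_p)
    small <- random_rigid_transform(3, 1, seed = 950 + s)
    init <- compose_transforms(small, pair$ground_truth)  # perturbed truth
    res <- icp_register(P[seq_len(min(nrow(P), nrow(Q))), ], Q,
                        init = init, mu = 1e-8, max_iter = 100)
    expect_lte(res$residuals[length(res$residuals)], res$residuals[2] + 1e-12)
  }
})

test_that("icp results expose tidy/glance/autoplot interfaces", {
  P <- random_points(10, seed = 52)
  res <- icp_register(P, P)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "residual", "objective"))
  gl <- glance(res)
  expect_equal(gl$iterations, 2L)
  expect_true(gl$converged)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})

test_that("surface assignment projects onto the mesh exactly", {
  tet <- tetrahedron_mesh()
  pr <- closest_point_on_mesh(tet, tet$vertices)
  expect_equal(pr$distance, rep(0, 4), tolerance = 1e-12)

  # a point straight above a face centroid lands on that face
  cen <- colMeans(tet$vertices[tet$faces[1, ], ])
  nrm <- dentalign:::face_normals(tet)[1, ]
  pt <- cen + 0.3 * nrm
  pr2 <- closest_point_on_mesh(tet, matrix(pt, 1))
  expect_equal(unname(pr2$distance), 0.3, tolerance = 1e-12)
  expect_equal(as.numeric(pr2$points), cen, tolerance = 1e-12)

  # brute-force oracle: dense barycentric sampling of every face
  set.seed(53)
  queries <- matrix(rnorm(15, sd = 1), ncol = 3)
  u <- seq(0, 1, length.out = 60)
  grid <- expand.grid(a = u, b = u)
  grid <- grid[grid$a + grid$b <= 1, ]
  samples <- do.call(rbind, lapply(seq_len(nrow(tet$faces)), function(fi) {
    tri <- tet$vertices[tet$faces[fi, ], ]
    cbind(grid$a, grid$b, 1 - grid$a - grid$b) %*% tri
  }))
  pr3 <- closest_point_on_mesh(tet, queries)
  for (i in seq_len(nrow(queries))) {
    oracle <- min(sqrt(rowSums(sweep(samples, 2, queries[i, ])^2)))
    expect_lte(pr3$distance[i], oracle + 1e-9)
    expect_gte(pr3$distance[i], oracle - 0.05)  # sampling resolution
  }
})
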