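test_that("vertex angles follow the incident faces", {
  g <- flat_grid_mesh(n = 5, size = 4)
  interior <- which(!g$boundary)[1]
  expect_equal(sum(vertex_angles(g, interior)), 2 * pi, tolerance = 1e-12)

  tet <- tetrahedron_mesh()
  a <- vertex_angles(tet, 1)
  expect_length(a, 3)
  expect_equal(a, rep(pi / 3, 3), tolerance = 1e-12)

  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1L, 2L, 3L), 1), welded = TRUE)
  expect_length(vertex_angles(tri, 1), 1)

  iso <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5)),
                       matrix(c(1L, 2L, 3L), 1), welded = TRUE)
  expect_error(vertex_angles(iso, 4), class = "dentalign_error_geometry")
})

test_that("angle-deficit curvature matches hand-derived values", {
  g <- flat_grid_mesh(n = 7, size = 6)
  for (v in which(!g$boundary)[1:5]) {
    expect_equal(vertex_curvature(g, v), 0, tolerance = 1e-12)
  }

  # regular unit tetrahedron apex: deficit pi over one-ring area 3*sqrt(3)/4
  tet <- tetrahedron_mesh()
  expect_equal(vertex_curvature(tet, 1), 4 * pi / (3 * sqrt(3)),
               tolerance = 1e-12)
  # barycentric mode divides by a third of the ring area
  expect_equal(vertex_curvature(tet, 1, area = "barycentric"),
               3 * 4 * pi / (3 * sqrt(3)), tolerance = 1e-12)

  # every welded cube corner: three right angles -> deficit pi/2 over its
  # one-ring area (brute-forced from the fixture coordinates)
  cube <- weld_vertices(cube_mesh_soup())
  fa <- dentalign:::face_areas(cube)
  for (v in seq_len(8)) {
    expect_equal(sum(vertex_angles(cube, v)), 3 * pi / 2, tolerance = 1e-12)
    ring <- sum(fa[cube$vertex_faces[[v]]])
    expect_equal(vertex_curvature(cube, v), (pi / 2) / ring,
                 tolerance = 1e-12)
  }
})

test_that("boundary vertices are flagged, with an optional diagnostic value", {
  g <- flat_grid_mesh(n = 5, size = 4)
  b <- which(g$boundary)[1]
  expect_error(vertex_curvature(g, b), class = "dentalign_error_geometry")
  expect_true(is.finite(vertex_curvature(g, b, boundary_ok = TRUE)))
  tab <- all_curvatures(g)
  expect_true(all(is.na(tab$curvature[tab$boundary])))
  expect_true(all(tab$curvature[!tab$boundary] == 0))
  tab2 <- all_curvatures(g, boundary = "diagnostic")
  expect_true(all(is.finite(tab2$curvature)))
})

test_that("all_curvatures agrees with per-vertex evaluation on a bumpy phantom", {
  ph <- make_phantom(n_cusps = 3, grid_res = 24, seed = 11)
  tab <- all_curvatures(ph)
  interior <- which(!ph$boundary)
  pick <- interior[seq(1, length(interior), by = 17)]
  for (v in pick) {
    expect_equal(tab$curvature[v], vertex_curvature(ph, v), tolerance = 1e-9)
  }
  # curvature maxima sit at the planted bump apices
  cusps <- attr(ph, "cusps")
  top <- tab[order(tab$curvature, decreasing = TRUE)[1:3], ]
  d_to_cusp <- sapply(seq_len(nrow(top)), function(i) {
    min(sqrt((top$x[i] - cusps$cx)^2 + (top$y[i] - cusps$cy)^2))
  })
  expect_true(all(d_to_cusp < 1.5))
})

test_that("total angle deficit of closed genus-0 meshes is 4*pi (Gauss-Bonnet)", {
  cube <- weld_vertices(cube_mesh_soup())
  expect_equal(sum(all_curvatures(cube)$deficit), 4 * pi, tolerance = 1e-9)
  sphere <- make_bumpy_sphere(subdiv = 2, n_bumps = 4, seed = 2)
  expect_equal(sum(all_curvatures(sphere)$deficit), 4 * pi, tolerance = 1e-9)
})

test_that("curvature is rigid-invariant and scales as 1/s^2", {
  ph <- make_phantom(n_cusps = 2, grid_res = 20, seed = 3)
  base <- all_curvatures(ph)$curvature
  interior <- !ph$boundary
  for (s in 1:10) {
    tr <- random_rigid_transform(180, 50, seed = s)
    moved <- transform_mesh(tr, ph)
    k2 <- all_curvatures(moved)$curvature
    expect_equal(k2[interior], base[interior], tolerance = 1e-9)

    scale <- runif(1, 0.5, 3)
    scaled <- ph
    scaled$vertices <- ph$vertices * scale
    k3 <- all_curvatures(scaled)$curvature
    expect_equal(k3[interior], base[interior] / scale^2, tolerance = 1e-9)
  }
})

test_that("feature extraction thresholds curvature and is monotone in alpha", {
  flat <- flat_grid_mesh(n = 10, size = 8)
  expect_equal(nrow(extract_features(flat, alpha = 0.01)$table), 0)

  ph <- make_phantom(n_cusps = 3, grid_res = 32, seed = 4)
  tab <- all_curvatures(ph)
  fs <- extract_features(ph, alpha = 0.05)
  # brute-force threshold oracle
  manual <- which(!ph$boundary & !is.na(tab$curvature) & tab$curvature > 0.05)
  expect_equal(fs$table$vertex, manual)
  expect_false(is.unsorted(fs$table$vertex))

  fs_loose <- extract_features(ph, alpha = 0.02)
  expect_true(all(fs$table$vertex %in% fs_loose$table$vertex))

  # signed selection also keeps saddle-like (negative-deficit) vertices
  fs_signed <- extract_features(ph, alpha = 0.05, signed = TRUE)
  expect_true(all(fs$table$vertex %in% fs_signed$table$vertex))
  neg <- which(!ph$boundary & tab$curvature < -0.05)
  expect_true(all(neg %in% fs_signed$table$vertex))

  # feature points concentrate within the planted bump footprints
  cusps <- attr(ph, "cusps")
  d_min <- sapply(seq_len(nrow(fs$table)), function(i) {
    min(sqrt((fs$table$x[i] - cusps$cx)^2 + (fs$table$y[i] - cusps$cy)^2))
  })
  expect_true(all(d_min < 3 * max(cusps$sigma)))
})

test_that("feature sets export to JSON with positions and curvatures", {
  ph <- make_phantom(n_cusps = 2, grid_res = 20, seed = 6)
  fs <- extract_features(ph, alpha = 0.05)
  f <- withr::local_tempfile(fileext = ".json")
  write_features_json(fs, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$alpha, 0.05)
  expect_equal(nrow(obj$features), nrow(fs$table))
  expect_equal(obj$features$curvature, fs$table$curvature)
})
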