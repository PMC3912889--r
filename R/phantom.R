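#' Small deterministic mesh fixtures
#'
#' `cube_mesh_soup()` returns an axis-aligned cube tessellated as 12
#' facets in triangle-soup form (36 private vertices), as a binary STL
#' reader would produce it. `tetrahedron_mesh()` returns a welded regular
#' tetrahedron with unit edges. `flat_grid_mesh()` returns a welded flat
#' triangulated grid in the z = 0 plane.
#'
#' @param size Edge length (cube) or side length (grid) in mm.
#' @param n Grid vertices per side (grid).
#' @return A [triangle_mesh()].
#' @export
cube_mesh_soup <- function(size = 1) {
  v <- as.matrix(expand.grid(x = c(0, size), y = c(0, size), z = c(0, size)))
  dimnames(v) <- NULL
  # corner ids in expand.grid order: x fastest, then y, then z
  id <- function(x, y, z) 1 + x + 2 * y + 4 * z
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(
    quad(id(0, 0, 0), id(0, 1, 0), id(1, 1, 0), id(1, 0, 0)),  # z = 0, normal -z
    quad(id(0, 0, 1), id(1, 0, 1), id(1, 1, 1), id(0, 1, 1)),  # z = 1, normal +z
    quad(id(0, 0, 0), id(1, 0, 0), id(1, 0, 1), id(0, 0, 1)),  # y = 0
    quad(id(0, 1, 0), id(0, 1, 1), id(1, 1, 1), id(1, 1, 0)),  # y = 1
    quad(id(0, 0, 0), id(0, 0, 1), id(0, 1, 1), id(0, 1, 0)),  # x = 0
    quad(id(1, 0, 0), id(1, 1, 0), id(1, 1, 1), id(1, 0, 1))   # x = 1
  )
  soup_v <- v[as.vector(t(f)), , drop = FALSE]
  soup_f <- matrix(seq_len(nrow(soup_v)), ncol = 3, byrow = TRUE)
  triangle_mesh(soup_v, soup_f)
}

#' @rdname cube_mesh_soup
#' @export
tetrahedron_mesh <- function(size = 1) {
  v <- size * rbind(
    c(0, 0, 0),
    c(1, 0, 0),
    c(0.5, sqrt(3) / 2, 0),
    c(0.5, sqrt(3) / 6, sqrt(6) / 3)
  )
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  triangle_mesh(v, f, welded = TRUE)
}

#' @rdname cube_mesh_soup
#' @export
flat_grid_mesh <- function(n = 10, size = 10) {
  grid_height_mesh(matrix(0, n, n), size)
}

# Triangulate an nx x ny height field over [-size/2, size/2]^2 into a
# welded mesh; vertices row-major (x fastest). `z` is nx x ny.
grid_height_mesh <- function(z, size) {
  nx <- nrow(z)
  ny <- ncol(z)
  xs <- seq(-size / 2, size / 2, length.out = nx)
  ys <- seq(-size / 2, size / 2, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), as.vector(z))
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  f <- rbind(
    cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
    cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
  )
  m <- triangle_mesh(v, f, welded = TRUE)
  attr(m, "grid") <- list(nx = nx, ny = ny, size = size)
  m
}

#' Dental-arch-like synthetic phantom surface
#'
#' Generates a triangulated height field emulating an occlusal surface:
#' a smooth arch-like dome plus `n_cusps` Gaussian bumps ("cusps") with
#' seeded random centers, heights and widths. The bump apices are the
#' curvature maxima, so curvature-thresholded feature extraction finds
#' them; the dome's curvature stays well below the default feature
#' threshold.
#'
#' @param n_cusps Number of cusps (`>= 1`; 0 gives the cusp-free dome).
#' @param base_size Side length of the square domain, mm (default 30).
#' @param grid_res Vertices per side (`>= 16`, default 64).
#' @param seed Integer seed; identical seeds reproduce bit-identical
#'   meshes.
#' @param cusp_height Range (min, max) of cusp heights, mm.
#' @param cusp_width Range (min, max) of cusp Gaussian widths (sigma),
#'   mm.
#' @return A welded [triangle_mesh()] with attributes `grid` (the height
#'   field layout) and `cusps` (tibble of planted `cx`, `cy`, `height`,
#'   `sigma`).
#' @export
#' @examples
#' ph <- make_phantom(n_cusps = 4, seed = 1)
#' fs <- extract_features(ph, alpha = 0.01)
make_phantom <- function(n_cusps = 4, base_size = 30, grid_res = 64,
                         seed = 1, cusp_height = c(1.5, 3),
                         cusp_width = c(1.2, 2)) {
  stopifnot(n_cusps >= 0, grid_res >= 16, base_size > 0)
  L <- base_size
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    if (n_cusps > 0) {
      lim <- 0.25 * L
      min_sep <- 0.15 * L
      tries <- 0
      while (nrow(centers) < n_cusps && tries < 1000) {
        cand <- runif(2, -lim, lim)
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_sep) {
          centers <- rbind(centers, cand)
        }
        tries <- tries + 1
      }
      if (nrow(centers) < n_cusps) {
        stop_dentalign("dentalign_error_generation",
                       "could not place cusps with the required separation")
      }
    }
    heights <- if (n_cusps > 0) runif(n_cusps, cusp_height[1], cusp_height[2]) else numeric(0)
    sigmas <- if (n_cusps > 0) runif(n_cusps, cusp_width[1], cusp_width[2]) else numeric(0)

    xs <- seq(-L / 2, L / 2, length.out = grid_res)
    ys <- seq(-L / 2, L / 2, length.out = grid_res)
    X <- matrix(xs, grid_res, grid_res)
    Y <- matrix(ys, grid_res, grid_res, byrow = TRUE)
    Z <- 4 * cos(pi * X / L) * cos(pi * Y / L)      # smooth arch-like dome
    for (k in seq_len(n_cusps)) {
      Z <- Z + heights[k] *
        exp(-((X - centers[k, 1])^2 + (Y - centers[k, 2])^2) /
              (2 * sigmas[k]^2))
    }
    m <- grid_height_mesh(Z, L)
    attr(m, "cusps") <- tibble::tibble(
      cx = centers[, 1], cy = centers[, 2],
      height = heights, sigma = sigmas
    )
    m
  })
}

#' Closed bumpy sphere fixture
#'
#' A genus-0 closed surface: an icosphere (subdivided icosahedron
#' projected to a sphere) with seeded radial Gaussian bumps. Useful for
#' checks that need a closed mesh, e.g. the discrete Gauss-Bonnet
#' identity (total angle deficit `= 4 * pi`).
#'
#' @param subdiv Subdivision levels of the icosahedron (default 3).
#' @param radius Sphere radius, mm (default 10).
#' @param n_bumps Number of radial bumps (default 6; 0 for a plain
#'   sphere).
#' @param seed Integer seed.
#' @return A welded, closed [triangle_mesh()].
#' @export
make_bumpy_sphere <- function(subdiv = 3, radius = 10, n_bumps = 6,
                              seed = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    newv <- v
    newf <- matrix(0L, 4 * nf, 3)
    for (k in seq_len(nf)) {
      tri <- f[k, ]
      mids <- rbind((v[tri[1], ] + v[tri[2], ]) / 2,
                    (v[tri[2], ] + v[tri[3], ]) / 2,
                    (v[tri[3], ] + v[tri[1], ]) / 2)
      base <- nrow(newv)
      newv <- rbind(newv, mids)
      a <- base + 1L; b <- base + 2L; c_ <- base + 3L
      newf[(4 * k - 3):(4 * k), ] <- rbind(
        c(tri[1], a, c_), c(tri[2], b, a), c(tri[3], c_, b), c(a, b, c_)
      )
    }
    v <- newv
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2))
  m <- weld_vertices(triangle_mesh(v, f), tol = 1e-9)
  v <- m$vertices
  v <- v / sqrt(rowSums(v^2))
  r <- rep(radius, nrow(v))
  if (n_bumps > 0) {
    with_seed(seed, {
      for (k in seq_len(n_bumps)) {
        ctr <- rnorm(3)
        ctr <- ctr / sqrt(sum(ctr^2))
        amp <- runif(1, 0.05, 0.15) * radius
        width <- runif(1, 0.2, 0.4)
        ang <- acos(pmax(-1, pmin(1, v %*% ctr)))
        r <- r + amp * exp(-ang^2 / (2 * width^2))
      }
    })
  }
  triangle_mesh(v * r, m$faces, welded = TRUE)
}

#' Seeded random rigid transform with bounded magnitude
#'
#' Draws a rotation about a uniformly random axis by an angle uniform on
#' `[0, rotation_max]` degrees, and a translation along a uniformly
#' random direction with magnitude uniform on `[0, translation_max]` mm.
#' Bounds of zero give the exact identity.
#'
#' @param rotation_max Maximum rotation angle, degrees (`>= 0`).
#' @param translation_max Maximum translation norm, mm (`>= 0`).
#' @param seed Integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(rotation_max = 30, translation_max = 20,
                                   seed = NULL) {
  stopifnot(rotation_max >= 0, translation_max >= 0)
  draw <- function() {
    axis <- rnorm(3)
    while (sum(axis^2) < 1e-12) axis <- rnorm(3)
    angle <- runif(1, 0, rotation_max) * pi / 180
    R <- if (rotation_max == 0) diag(3) else rotation_about_axis(axis, angle)
    dir <- rnorm(3)
    while (sum(dir^2) < 1e-12) dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    Tt <- if (translation_max == 0) c(0, 0, 0) else
      dir * runif(1, 0, translation_max)
    rigid_transform(R, Tt, tol = 1e-9)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a registration phantom pair with known ground truth
#'
#' From a full phantom surface, builds a mesh pair emulating a clinical
#' cross-modality mismatch: the reference is a grid-decimated version of
#' the full surface (the coarse, full-coverage CT analogue) and the
#' target is a dense crop of the cusp-bearing region (the
#' high-resolution, partial-coverage scanner analogue), displaced by a
#' seeded random rigid transform with optional Gaussian vertex noise
#' applied along vertex normals (surface-measurement analogue) or
#' isotropically. The recorded ground truth maps target points back into
#' the reference frame.
#'
#' @param phantom A mesh from [make_phantom()] (must carry its height
#'   field `grid` attribute).
#' @param rotation_max,translation_max Displacement bounds for
#'   [random_rigid_transform()] (degrees, mm).
#' @param crop_fraction Fraction of the surface area kept in the target
#'   crop, `(0, 1]` (default 0.5). The crop window is centered on the
#'   planted cusps.
#' @param decimate_keep_fraction Approximate fraction of vertices kept in
#'   the reference, `(0, 1]` (default 0.3; realized by grid coarsening,
#'   so the achieved fraction is `1/ceiling(1/sqrt(f))^2`).
#' @param noise_sd Gaussian vertex-noise standard deviation, mm (default
#'   0.05).
#' @param noise_mode `"normal"` (along vertex normals, default) or
#'   `"isotropic"`.
#' @param seed Integer seed; the same seed reproduces the pair exactly.
#' @return An object of class `phantom_pair`: list with `reference`,
#'   `target` (welded [triangle_mesh()]), `ground_truth` (the
#'   [rigid_transform()] mapping target into the reference frame),
#'   `displacement` (its inverse, as applied), `noise_sd`, `seed`,
#'   `cusps`, `crop_window`.
#' @export
make_pair <- function(phantom, rotation_max = 30, translation_max = 20,
                      crop_fraction = 0.5, decimate_keep_fraction = 0.3,
                      noise_sd = 0.05, noise_mode = c("normal", "isotropic"),
                      seed = 1) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(phantom, "triangle_mesh"),
            crop_fraction > 0, crop_fraction <= 1,
            decimate_keep_fraction > 0, decimate_keep_fraction <= 1,
            noise_sd >= 0)
  g <- attr(phantom, "grid")
  if (is.null(g)) {
    stop_dentalign("dentalign_error_generation",
                   "phantom lacks its height-field grid attribute; use make_phantom()")
  }
  cusps <- attr(phantom, "cusps")

  # reference: grid coarsening
  step <- max(1L, ceiling(1 / sqrt(decimate_keep_fraction)))
  keep_i <- seq(1L, g$nx, by = step)
  keep_j <- seq(1L, g$ny, by = step)
  zfull <- matrix(phantom$vertices[, 3], g$nx, g$ny)
  reference <- grid_height_mesh(zfull[keep_i, keep_j, drop = FALSE], g$size)
  # coarsened grid spans the same footprint only approximately at the far
  # edge; rebuild coordinates from the kept rows/columns instead
  xs <- seq(-g$size / 2, g$size / 2, length.out = g$nx)[keep_i]
  ys <- seq(-g$size / 2, g$size / 2, length.out = g$ny)[keep_j]
  reference$vertices[, 1] <- rep(xs, times = length(ys))
  reference$vertices[, 2] <- rep(ys, each = length(xs))
  attr(reference, "cusps") <- cusps

  # target: dense crop around the cusps
  w <- g$size * sqrt(crop_fraction)
  ctr <- if (!is.null(cusps) && nrow(cusps) > 0) {
    c(mean(cusps$cx), mean(cusps$cy))
  } else {
    c(0, 0)
  }
  half <- g$size / 2
  ctr <- pmin(pmax(ctr, -half + w / 2), half - w / 2)
  v <- phantom$vertices
  inside <- abs(v[, 1] - ctr[1]) <= w / 2 & abs(v[, 2] - ctr[2]) <= w / 2
  if (!is.null(cusps) && nrow(cusps) > 0) {
    covered <- abs(cusps$cx - ctr[1]) <= w / 2 - cusps$sigma &
      abs(cusps$cy - ctr[2]) <= w / 2 - cusps$sigma
    if (!any(covered)) {
      stop_dentalign("dentalign_error_generation",
                     "crop window contains no planted cusp; pair would be unregistrable by features")
    }
  }
  f <- phantom$faces
  fkeep <- inside[f[, 1]] & inside[f[, 2]] & inside[f[, 3]]
  vids <- sort(unique(as.vector(f[fkeep, , drop = FALSE])))
  remap <- integer(nrow(v))
  remap[vids] <- seq_along(vids)
  crop <- triangle_mesh(v[vids, , drop = FALSE],
                        matrix(remap[f[fkeep, , drop = FALSE]], ncol = 3),
                        welded = TRUE)

  with_seed(seed, {
    disp <- random_rigid_transform(rotation_max, translation_max, seed = NULL)
    tv <- crop$vertices
    if (noise_sd > 0) {
      if (noise_mode == "normal") {
        vn <- vertex_normals(crop)
        tv <- tv + vn * rnorm(nrow(tv), sd = noise_sd)
      } else {
        tv <- tv + matrix(rnorm(3 * nrow(tv), sd = noise_sd), ncol = 3)
      }
    }
    target <- triangle_mesh(transform_points(disp, tv), crop$faces,
                            welded = TRUE)
    structure(
      list(
        reference = reference,
        target = target,
        ground_truth = invert_transform(disp),
        displacement = disp,
        noise_sd = noise_sd,
        seed = seed,
        cusps = cusps,
        crop_window = list(center = ctr, width = w)
      ),
      class = "phantom_pair"
    )
  })
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf(
    "<phantom_pair> reference %d vertices, target %d vertices, noise sd %g mm\n",
    nrow(x$reference$vertices), nrow(x$target$vertices), x$noise_sd
  ))
  cat(sprintf("  ground-truth rotation %.2f deg, translation %.2f mm\n",
              rotation_angle(x$ground_truth$R) * 180 / pi,
              sqrt(sum(x$ground_truth$T^2))))
  invisible(x)
}
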