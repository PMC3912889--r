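#' Rigid transform (rotation + translation)
#'
#' A proper rigid transform `q = R p + T`: `R` a 3x3 rotation matrix
#' (orthonormal, `det(R) = +1`), `T` a translation in mm. Points are
#' column vectors in the model `q = R p + T`; [transform_points()] applies
#' it to row-per-point matrices.
#'
#' @param R 3x3 rotation matrix. Default identity.
#' @param T Length-3 translation vector (mm). Default zero.
#' @param tol Validation tolerance on `max|R'R - I|` and `|det(R) - 1|`
#'   (default `1e-9`; loosen for transforms quoted at low precision).
#' @return An object of class `rigid_transform`.
#' @export
#' @examples
#' t1 <- rigid_transform(T = c(1, 2, 3))
#' transform_points(t1, rbind(c(0, 0, 0)))
rigid_transform <- function(R = diag(3), T = c(0, 0, 0), tol = 1e-9) {
  R <- unname(as.matrix(R))
  T <- unname(as.numeric(T))
  stopifnot(all(dim(R) == c(3, 3)), length(T) == 3)
  chk <- validate_rotation(R, tol = tol)
  if (!chk$valid) {
    stop_dentalign(
      "dentalign_error_geometry",
      sprintf("not a proper rotation: max|R'R - I| = %.3g, det = %.6f (tol %.3g)",
              chk$orthonormality_deviation, chk$determinant, tol)
    )
  }
  structure(list(R = R, T = T), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>  q = R p + T\n")
  cat("R =\n")
  print(round(x$R, 6))
  cat("T =", paste(signif(x$T, 7), collapse = " "), "(mm)\n")
  invisible(x)
}

#' Validate a rotation matrix
#'
#' Checks orthonormality (`max|M'M - I| <= tol`) and properness
#' (`|det(M) - 1| <= tol`). Useful as a consistency gate for externally
#' supplied transforms, e.g. matrices quoted in reports at 5 decimal
#' places.
#'
#' @param M A 3x3 matrix.
#' @param tol Tolerance (default `1e-9`).
#' @return A list: `valid` (logical), `orthonormality_deviation`
#'   (`max|M'M - I|`), `determinant`.
#' @export
validate_rotation <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(3, 3)))
  dev <- max(abs(crossprod(M) - diag(3)))
  d <- det(M)
  list(
    valid = dev <= tol && abs(d - 1) <= tol,
    orthonormality_deviation = dev,
    determinant = d
  )
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points Numeric matrix, one point per row (n x 3), or a length-3
#'   vector.
#' @return Transformed points, same shape as the input (`R p + T` per
#'   point).
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, ncol = 3) else as.matrix(points)
  stopifnot(ncol(p) == 3)
  out <- p %*% t(transform$R) +
    matrix(transform$T, nrow(p), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Apply a rigid transform to a mesh
#'
#' @param transform A [rigid_transform()].
#' @param mesh A [triangle_mesh()].
#' @return The mesh with transformed vertex coordinates (same topology).
#' @export
transform_mesh <- function(transform, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  mesh$vertices <- transform_points(transform, mesh$vertices)
  mesh
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform that applies `t1` first,
#' then `t2` (`q = R2 (R1 p + T1) + T2`).
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(t2, t1) {
  stopifnot(inherits(t2, "rigid_transform"), inherits(t1, "rigid_transform"))
  rigid_transform(t2$R %*% t1$R, as.numeric(t2$R %*% t1$T) + t2$T,
                  tol = 1e-6)
}

#' @rdname compose_transforms
#' @param transform A [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$R)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$T), tol = 1e-6)
}

#' Sum of squared correspondence residuals
#'
#' The registration objective `e = sum_i || Q_i - (R P_i + T) ||^2` (mm^2)
#' for paired point sets under a candidate transform.
#'
#' @param P,Q Matrices of corresponding points (n x 3), `Q[i, ]` paired
#'   with `P[i, ]`.
#' @param transform A [rigid_transform()].
#' @return Nonnegative scalar (mm^2); zero iff `Q = transform(P)` exactly.
#' @export
squared_error <- function(P, Q, transform) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) {
    stop_dentalign("dentalign_error_geometry",
                   sprintf("point sets differ in length (%d vs %d)",
                           nrow(P), nrow(Q)))
  }
  d <- Q - transform_points(transform, P)
  sum(d^2)
}

#' Least-squares rigid transform between paired point sets
#'
#' Estimates the proper rigid transform minimizing
#' `sum_i || Q_i - (R P_i + T) ||^2` by the singular-value-decomposition
#' method: demean both sets, take the SVD of the cross-covariance
#' `H = sum_i (P_i - mean(P)) (Q_i - mean(Q))'`, set `R = V U'` (with the
#' singular direction of smallest singular value negated when the
#' orthogonal optimum is a reflection, so `det(R) = +1` always), and
#' `T = mean(Q) - R mean(P)`.
#'
#' @param P Source points (n x 3, n >= 3, not all collinear).
#' @param Q Corresponding points (n x 3), `Q[i, ]` paired with `P[i, ]`.
#' @return A [rigid_transform()] with `det(R) = +1`.
#' @export
#' @examples
#' P <- matrix(rnorm(30), ncol = 3)
#' t0 <- rigid_transform(rotation_about_axis(c(0, 0, 1), pi / 3), c(1, 2, 3))
#' estimate_rigid_svd(P, transform_points(t0, P))
estimate_rigid_svd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) {
    stop_dentalign("dentalign_error_geometry",
                   sprintf("point sets differ in length (%d vs %d)",
                           nrow(P), nrow(Q)))
  }
  if (nrow(P) < 3) {
    stop_dentalign("dentalign_error_geometry",
                   "need at least 3 correspondences to estimate a rigid transform")
  }
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  # collinear source points leave the rotation about their axis undetermined
  sp <- svd(Pc)$d
  if (sp[2] < 1e-12 * max(1, sp[1])) {
    stop_dentalign("dentalign_error_geometry",
                   "source points are collinear; rotation is not identifiable")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  rigid_transform(R, cq - as.numeric(R %*% cp), tol = 1e-6)
}

#' Rotation matrix about an axis
#'
#' Rodrigues' formula for the rotation by `angle` radians about the unit
#' direction of `axis`.
#'
#' @param axis Length-3 axis (normalized internally; must be nonzero).
#' @param angle Angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  stopifnot(n > 0)
  a <- a / n
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' Recovers the angle (radians, in `[0, pi]`) from the trace,
#' `cos(theta) = (tr(R) - 1) / 2`.
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in radians.
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(as.matrix(R))) - 1) / 2)))
}

#' Read/write a rigid transform as JSON
#'
#' Schema: `{"R": [[...3x3 rows...]], "T": [x, y, z],
#' "convention": "q = R p + T"}`.
#'
#' @param transform A [rigid_transform()].
#' @param path File path.
#' @param tol Validation tolerance for matrices read from file (default
#'   `1e-6`; external files may carry rounded entries).
#' @return `write_transform_json()`: `path` invisibly;
#'   `read_transform_json()`: a [rigid_transform()].
#' @export
write_transform_json <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  obj <- list(
    R = lapply(seq_len(3), function(i) transform$R[i, ]),
    T = transform$T,
    convention = "q = R p + T"
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path, tol = 1e-6) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- obj$R
  if (!is.matrix(R)) R <- do.call(rbind, lapply(obj$R, unlist))
  rigid_transform(R, as.numeric(obj$T), tol = tol)
}
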