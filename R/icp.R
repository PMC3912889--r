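#' Unique nearest-neighbour correspondences
#'
#' Assigns to each query point `p_i` a distinct reference point: all
#' (query, reference) pairs are considered in globally ascending distance
#' order (ties broken by lower reference index, then lower query index)
#' and assigned greedily, each query taking its nearest still-unclaimed
#' reference point. Candidates come from a k-d tree; candidate lists grow
#' lazily, so the result equals the full greedy assignment over every
#' pair without materializing the distance matrix.
#'
#' @param reference Reference points `Q` (n_Q x 3).
#' @param query Query points `P` (n_P x 3), `n_P <= n_Q`.
#' @return A list: `index` (length n_P, the reference row assigned to
#'   each query point; no repeats), `distance` (mm).
#' @export
nearest_unique <- function(reference, query) {
  Q <- as.matrix(reference)
  P <- as.matrix(query)
  nq <- nrow(Q)
  np <- nrow(P)
  if (np > nq) {
    stop_dentalign("dentalign_error_geometry",
                   sprintf("query set larger than reference set (%d > %d); unique assignment impossible",
                           np, nq))
  }
  if (np == 0) return(list(index = integer(0), distance = numeric(0)))

  k0 <- min(nq, max(4L, ceiling(log2(np + 1)) + 1L))
  nn <- RANN::nn2(Q, P, k = k0)
  cand_idx <- nn$nn.idx
  cand_d <- nn$nn.dists
  kmax <- rep(k0, np)

  ptr <- rep(1L, np)
  assigned <- rep(NA_integer_, np)
  assigned_d <- rep(NA_real_, np)
  claimed <- rep(FALSE, nq)

  cur_d <- cand_d[, 1]
  cur_q <- cand_idx[, 1]
  active <- rep(TRUE, np)

  expand <- function(i) {
    # grow candidate list of query i
    newk <- min(nq, kmax[i] * 2L)
    nn_i <- RANN::nn2(Q, P[i, , drop = FALSE], k = newk)
    len <- length(nn_i$nn.idx)
    if (ncol(cand_idx) < newk) {
      cand_idx <<- cbind(cand_idx,
                         matrix(NA_integer_, np, newk - ncol(cand_idx)))
      cand_d <<- cbind(cand_d, matrix(NA_real_, np, newk - ncol(cand_d)))
    }
    cand_idx[i, seq_len(len)] <<- nn_i$nn.idx[1, ]
    cand_d[i, seq_len(len)] <<- nn_i$nn.dists[1, ]
    kmax[i] <<- newk
  }

  n_left <- np
  while (n_left > 0) {
    # globally smallest current candidate among unassigned queries;
    # ties: lower reference index, then lower query index
    act <- which(active)
    dmin <- min(cur_d[act])
    tied <- act[cur_d[act] == dmin]
    if (length(tied) > 1) {
      tied <- tied[order(cur_q[tied], tied)]
    }
    i <- tied[1]
    q <- cur_q[i]
    if (!claimed[q]) {
      assigned[i] <- q
      assigned_d[i] <- cur_d[i]
      claimed[q] <- TRUE
      active[i] <- FALSE
      cur_d[i] <- Inf
      n_left <- n_left - 1
    } else {
      repeat {
        ptr[i] <- ptr[i] + 1L
        if (ptr[i] > kmax[i]) {
          if (kmax[i] >= nq) {
            stop_dentalign("dentalign_error_geometry",
                           "exhausted reference candidates during unique assignment")
          }
          expand(i)
        }
        if (!claimed[cand_idx[i, ptr[i]]]) break
      }
      cur_q[i] <- cand_idx[i, ptr[i]]
      cur_d[i] <- cand_d[i, ptr[i]]
    }
  }
  list(index = assigned, distance = assigned_d)
}

#' Closest-point correspondences (non-unique)
#'
#' Classic nearest-neighbour assignment: each query point gets its
#' closest reference point, repeats allowed.
#'
#' @inheritParams nearest_unique
#' @return A list: `index`, `distance`.
#' @export
nearest_closest <- function(reference, query) {
  nn <- RANN::nn2(as.matrix(reference), as.matrix(query), k = 1)
  list(index = as.integer(nn$nn.idx[, 1]), distance = as.numeric(nn$nn.dists[, 1]))
}

#' Mean correspondence residual
#'
#' The stopping statistic `r = mean_i || p_i - D(i) ||` (mm): the mean
#' unsquared Euclidean distance between each point and its assigned
#' correspondent.
#'
#' @param P Points (n x 3).
#' @param D Corresponding points (n x 3), row i paired with `P[i, ]`.
#' @return Mean distance in mm; 0 iff all pairs coincide.
#' @export
mean_residual <- function(P, D) {
  P <- as.matrix(P); D <- as.matrix(D)
  if (nrow(P) != nrow(D)) {
    stop_dentalign("dentalign_error_geometry",
                   sprintf("point sets differ in length (%d vs %d)",
                           nrow(P), nrow(D)))
  }
  mean(sqrt(rowSums((P - D)^2)))
}

#' Iterative closest point refinement
#'
#' Refines an initial rigid transform aligning target points `P` to
#' reference points `Q`. Each iteration (i) transforms the current
#' points by the latest transform, (ii) finds correspondences in `Q` by
#' k-d tree search (unique by default: no reference point is matched
#' twice), (iii) computes the mean residual `r^(k+1)` and stops when
#' `|r^(k+1) - r^k| <= mu`, and otherwise (iv) estimates the incremental
#' rigid update by [estimate_rigid_svd()] between the current points and
#' their correspondents, accumulating it into the running transform.
#'
#' The first applied transform is `init` itself (typically the coarse
#' alignment); `r^0` is the residual of the untransformed points. Because
#' `init` is not an estimated update, the stopping comparison starts with
#' the residual after the first SVD update (otherwise an identity `init`
#' would satisfy `|r^1 - r^0| = 0` before any refinement).
#'
#' @param P Target points (n_P x 3, n_P >= 3).
#' @param Q Reference points (n_Q x 3, n_Q >= n_P for unique
#'   assignment), or a welded [triangle_mesh()] for
#'   `assignment = "surface"`.
#' @param init Initial [rigid_transform()] (default identity).
#' @param mu Convergence precision on the residual change, mm (default
#'   `1e-6`).
#' @param max_iter Iteration cap (default 100).
#' @param assignment `"unique"` (default), `"closest"`, or `"surface"`
#'   (correspondent = exactly closest point on the reference surface via
#'   [closest_point_on_mesh()], removing the vertex-sampling
#'   quantization of point matching when the reference mesh is much
#'   coarser than the target).
#' @return An object of class `icp_result`: list with `transform` (the
#'   cumulative [rigid_transform()] mapping original `P` into the `Q`
#'   frame, `init` included), `residuals` (mm, `r^0 .. r^K`),
#'   `objective` (mm^2, the summed squared correspondence error at each
#'   step), `iterations`, `converged`, `stop_reason`
#'   (`"tolerance"`/`"max_iter"`), `assignment`, `mu`.
#' @export
icp_register <- function(P, Q, init = rigid_transform(), mu = 1e-6,
                         max_iter = 100,
                         assignment = c("unique", "closest", "surface")) {
  assignment <- match.arg(assignment)
  P <- as.matrix(P)
  stopifnot(inherits(init, "rigid_transform"), max_iter >= 1)
  if (nrow(P) < 3) {
    stop_dentalign("dentalign_error_geometry",
                   sprintf("need at least 3 target points, have %d", nrow(P)))
  }
  if (assignment == "surface") {
    stopifnot(inherits(Q, "triangle_mesh"), Q$welded)
    match_fun <- function(pts) {
      pr <- closest_point_on_mesh(Q, pts)
      list(D = pr$points, distance = pr$distance)
    }
  } else {
    Q <- as.matrix(Q)
    if (assignment == "unique" && nrow(P) > nrow(Q)) {
      stop_dentalign("dentalign_error_geometry",
                     sprintf("unique assignment needs |P| <= |Q| (%d > %d)",
                             nrow(P), nrow(Q)))
    }
    raw_fun <- if (assignment == "unique") nearest_unique else nearest_closest
    match_fun <- function(pts) {
      m <- raw_fun(Q, pts)
      list(D = Q[m$index, , drop = FALSE], distance = m$distance)
    }
  }

  cum <- rigid_transform()          # applied so far (identity before init)
  pending <- init                   # transform to apply at the next step
  Pk <- P
  m0 <- match_fun(Pk)
  r <- mean_residual(Pk, m0$D)
  residuals <- r
  objective <- sum(m0$distance^2)
  converged <- FALSE
  iterations <- 0L

  for (k in seq_len(max_iter)) {
    cum <- compose_transforms(pending, cum)
    Pk <- transform_points(pending, Pk)
    mk <- match_fun(Pk)
    Dk <- mk$D
    r_new <- mean_residual(Pk, Dk)
    residuals <- c(residuals, r_new)
    objective <- c(objective, sum(mk$distance^2))
    iterations <- k
    # the first applied transform is init, not an estimated update, so the
    # tolerance is judged between successive estimated updates (otherwise
    # an identity init trivially satisfies |r^1 - r^0| = 0 and the loop
    # would never refine)
    if (k >= 2 && abs(r_new - r) <= mu) {
      converged <- TRUE
      break
    }
    r <- r_new
    pending <- tryCatch(
      estimate_rigid_svd(Pk, Dk),
      error = function(e) {
        stop_dentalign("dentalign_error_geometry",
                       sprintf("transform estimation failed at iteration %d: %s",
                               k, conditionMessage(e)))
      }
    )
  }

  structure(
    list(
      transform = cum,
      residuals = residuals,
      objective = objective,
      iterations = iterations,
      converged = converged,
      stop_reason = if (converged) "tolerance" else "max_iter",
      assignment = assignment,
      mu = mu
    ),
    class = "icp_result"
  )
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf(
    "<icp_result> %d iteration(s), %s (%s assignment)\n",
    x$iterations,
    if (x$converged) sprintf("converged (|dr| <= %g mm)", x$mu)
    else "stopped at max_iter",
    x$assignment
  ))
  cat(sprintf("  residual: %.6g -> %.6g mm\n",
              x$residuals[1], x$residuals[length(x$residuals)]))
  invisible(x)
}

#' Tidy an ICP result into its iteration history
#'
#' @param x An `icp_result`.
#' @param ... Unused.
#' @return A tibble: `iteration` (0-based), `residual` (mm, mean
#'   correspondence distance), `objective` (mm^2, summed squared
#'   correspondence error).
#' @export
tidy.icp_result <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$residuals) - 1L,
    residual = x$residuals,
    objective = x$objective
  )
}

#' One-row summary of an ICP result
#'
#' @param x An `icp_result`.
#' @param ... Unused.
#' @return A one-row tibble: `iterations`, `converged`, `stop_reason`,
#'   `initial_residual`, `final_residual` (mm), `rotation_angle_deg`,
#'   `translation_norm` (mm) of the cumulative transform.
#' @export
glance.icp_result <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    stop_reason = x$stop_reason,
    initial_residual = x$residuals[1],
    final_residual = x$residuals[length(x$residuals)],
    rotation_angle_deg = rotation_angle(x$transform$R) * 180 / pi,
    translation_norm = sqrt(sum(x$transform$T^2))
  )
}

#' Plot the ICP residual history
#'
#' @param object An `icp_result`.
#' @param ... Unused.
#' @return A ggplot of the mean residual (mm) against iteration.
#' @export
autoplot.icp_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = iteration, y = residual)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "mean residual (mm)",
                  title = "ICP convergence") +
    ggplot2::theme_minimal()
}
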