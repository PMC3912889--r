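#' Two-phase rigid registration of a mesh pair
#'
#' Runs the full pipeline on a reference mesh (larger coverage, e.g. a
#' CT-derived crown-and-root surface) and a target mesh (smaller
#' coverage, higher resolution, e.g. an intraoral or plaster scan):
#' weld, angle-deficit curvature, curvature-thresholded feature
#' extraction on both meshes, three-point coarse alignment (landmarks
#' picked on the reference, matched in the target under curvature,
#' side-length and area constraints), then ICP refinement of the
#' target-to-reference transform on the feature point sets.
#'
#' The report carries the mean corresponding-point distance (each
#' transformed target vertex paired with its closest point on the
#' reference surface) after the coarse stage and after the precise
#' stage, so the improvement of the refinement is directly visible.
#'
#' @param reference,target [triangle_mesh()] objects or STL file paths.
#' @param alpha Feature curvature threshold, mm^-2 (default 0.01).
#' @param curv_tol Curvature-similarity gate for correspondence
#'   candidates, mm^-2 (default 0.00015; loosen for meshes of very
#'   different resolution — discrete curvature depends on triangle
#'   size).
#' @param dist_tol Side-length constraint threshold, mm (default 1).
#' @param area_tol Area constraint threshold, mm^2 (default 1).
#' @param mu ICP residual-change precision, mm (default `1e-6`).
#' @param max_iter ICP iteration cap (default 100).
#' @param weld_tol Vertex weld tolerance, mm (default `1e-6`).
#' @param assignment ICP correspondence mode, `"unique"` (default) or
#'   `"closest"`.
#' @param max_candidates Candidate cap per landmark in the triple search
#'   (default 64).
#' @param signed Use `|K| > alpha` feature selection (default `FALSE`).
#' @param curv_metric Curvature-similarity metric for correspondence
#'   candidates: `"absolute"` (default; raw mm^-2 differences, for
#'   same-resolution pairs) or `"quantile"` (rank within each feature
#'   set, robust across resolutions; `curv_tol` is then on the quantile
#'   scale, e.g. `0.15`). See [candidate_correspondences()].
#' @param refine_full After the feature-set ICP, run a second ICP of the
#'   full target vertex set against the reference surface
#'   (`assignment = "surface"`, correspondences on the triangulated
#'   surface rather than at vertices) to polish the transform (default
#'   `FALSE`). Recommended when the reference mesh is much coarser than
#'   the target: vertex-level matching then quantizes at the reference
#'   sampling scale.
#' @return An object of class `registration_report`: list with
#'   `transform` (final target-to-reference [rigid_transform()]),
#'   `coarse_transform`, `icp` (the [icp_register()] result), `triple`
#'   (the matched `correspondence_triple`), `reference_landmarks`
#'   (vertex ids), `n_reference_features`, `n_target_features`,
#'   `coarse_distance`, `precise_distance` (mm), `parameters`.
#' @export
#' @examples
#' ph <- make_phantom(seed = 3)
#' pair <- make_pair(ph, seed = 3)
#' \donttest{
#' rep <- register_meshes(pair$reference, pair$target, curv_tol = 1)
#' rep$precise_distance < rep$coarse_distance
#' }
register_meshes <- function(reference, target, alpha = 0.01,
                            curv_tol = 0.00015, dist_tol = 1.0,
                            area_tol = 1.0, mu = 1e-6, max_iter = 100,
                            weld_tol = 1e-6,
                            assignment = c("unique", "closest"),
                            max_candidates = 64, signed = FALSE,
                            curv_metric = c("absolute", "quantile"),
                            refine_full = FALSE) {
  assignment <- match.arg(assignment)
  curv_metric <- match.arg(curv_metric)
  params <- list(alpha = alpha, curv_tol = curv_tol, dist_tol = dist_tol,
                 area_tol = area_tol, mu = mu, max_iter = max_iter,
                 weld_tol = weld_tol, assignment = assignment,
                 max_candidates = max_candidates, signed = signed,
                 curv_metric = curv_metric, refine_full = refine_full)
  stopifnot(alpha > 0, curv_tol > 0, dist_tol > 0, area_tol > 0, mu > 0,
            max_iter >= 1)

  load_mesh <- function(x, what) {
    with_stage(paste0("input (", what, ")"), {
      m <- if (is.character(x)) read_stl(x) else x
      stopifnot(inherits(m, "triangle_mesh"))
      if (!m$welded) m <- weld_vertices(m, tol = weld_tol) else m
    })
  }
  ref <- load_mesh(reference, "reference")
  tgt <- load_mesh(target, "target")

  fs_ref <- with_stage("feature extraction (reference)",
                       extract_features(ref, alpha = alpha, signed = signed))
  fs_tgt <- with_stage("feature extraction (target)",
                       extract_features(tgt, alpha = alpha, signed = signed))

  coarse <- with_stage("coarse registration", {
    lm <- select_reference_points(fs_ref)
    lm_rows <- match(lm, fs_ref$table$vertex)
    m_pts <- as.matrix(fs_ref$table[lm_rows, c("x", "y", "z")])
    m_curv <- fs_ref$table$curvature[lm_rows]
    if (curv_metric == "quantile") {
      m_curv <- stats::ecdf(fs_ref$table$curvature)(m_curv)
    }
    trip <- match_triple(m_pts, m_curv, fs_tgt,
                         curv_tol = curv_tol, dist_tol = dist_tol,
                         area_tol = area_tol,
                         max_candidates = max_candidates,
                         metric = curv_metric,
                         ref_features = fs_ref,
                         n_hypotheses = if (refine_full) 5 else 1)
    # frames give the reference-to-target map; registration needs its inverse
    t_m2n <- coarse_transform(m_pts, trip$target_points)
    if (!is.null(trip$hypotheses) && length(trip$hypotheses) > 1) {
      # near-tied poses (e.g. symmetry flips of the feature layout) are
      # re-ranked after a brief feature-to-surface refinement from each:
      # the true pose refines to the noise floor, wrong ones plateau
      scores <- vapply(trip$hypotheses, function(h) {
        icp_h <- icp_register(feature_points(fs_ref), tgt, init = h$pose,
                              mu = mu, max_iter = 30,
                              assignment = "surface")
        icp_h$residuals[length(icp_h$residuals)]
      }, numeric(1))
      best <- which.min(scores)
      trip$target_vertices <- trip$hypotheses[[best]]$target_vertices
      trip$target_points <- trip$hypotheses[[best]]$target_points
      t_m2n <- coarse_transform(m_pts, trip$target_points)
    }
    list(landmarks = lm, triple = trip, init = invert_transform(t_m2n))
  })

  Qf <- feature_points(fs_ref)
  Pf <- feature_points(fs_tgt)

  # the moving set P must be the smaller one (|P| <= |Q|); when the target
  # carries more features than the reference (dense scan vs coarse CT),
  # refine in the reference-to-target direction and invert afterwards
  swap <- nrow(Pf) > nrow(Qf)
  icp <- with_stage("precise registration (ICP)", {
    if (swap) {
      icp_register(Qf, Pf, init = invert_transform(coarse$init), mu = mu,
                   max_iter = max_iter, assignment = assignment)
    } else {
      icp_register(Pf, Qf, init = coarse$init, mu = mu,
                   max_iter = max_iter, assignment = assignment)
    }
  })

  final <- if (swap) invert_transform(icp$transform) else icp$transform
  icp_full <- NULL
  if (refine_full) {
    icp_full <- with_stage("surface refinement (ICP)", {
      # leg 1: reference features against the dense target surface —
      # these correspondences are nearly exact (the features lie on the
      # common surface), giving a wide, well-behaved basin
      leg1 <- icp_register(Qf, tgt, init = invert_transform(final),
                           mu = mu, max_iter = max_iter,
                           assignment = "surface")
      # leg 2: all target vertices against the reference surface — the
      # high-count polish at the measurement-noise floor
      icp_register(tgt$vertices, ref,
                   init = invert_transform(leg1$transform),
                   mu = mu, max_iter = max_iter,
                   assignment = "surface")
    })
    final <- icp_full$transform
  }

  # per-stage accuracy metric: mean distance from the transformed target
  # vertices to their corresponding (closest) points on the reference
  # surface
  dist_under <- function(tr) {
    moved <- transform_points(tr, tgt$vertices)
    mean(closest_point_on_mesh(ref, moved)$distance)
  }
  coarse_distance <- dist_under(coarse$init)
  precise_distance <- dist_under(final)

  structure(
    list(
      transform = final,
      coarse_transform = coarse$init,
      icp = icp,
      icp_full = icp_full,
      triple = coarse$triple,
      reference_landmarks = coarse$landmarks,
      n_reference_features = nrow(fs_ref$table),
      n_target_features = nrow(fs_tgt$table),
      coarse_distance = coarse_distance,
      precise_distance = precise_distance,
      parameters = params
    ),
    class = "registration_report"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(
    expr,
    dentalign_error = function(e) {
      cls <- class(e)[1]
      stop_dentalign(cls, sprintf("[%s] %s", stage, conditionMessage(e)),
                     stage = stage)
    }
  )
}

#' @export
print.registration_report <- function(x, ...) {
  cat("<registration_report>\n")
  cat(sprintf("  features: %d (reference), %d (target)\n",
              x$n_reference_features, x$n_target_features))
  cat(sprintf("  coarse mean distance:  %.4f mm\n", x$coarse_distance))
  cat(sprintf("  precise mean distance: %.4f mm  (%d ICP iteration(s), %s)\n",
              x$precise_distance, x$icp$iterations,
              if (x$icp$converged) "converged" else "max_iter"))
  cat(sprintf("  final rotation %.3f deg, translation %.3f mm\n",
              rotation_angle(x$transform$R) * 180 / pi,
              sqrt(sum(x$transform$T^2))))
  invisible(x)
}

#' @describeIn register_meshes One-row summary of a registration report.
#' @param x A `registration_report`.
#' @param ... Unused.
#' @export
glance.registration_report <- function(x, ...) {
  tibble::tibble(
    n_reference_features = x$n_reference_features,
    n_target_features = x$n_target_features,
    coarse_distance = x$coarse_distance,
    precise_distance = x$precise_distance,
    icp_iterations = x$icp$iterations,
    converged = x$icp$converged,
    rotation_angle_deg = rotation_angle(x$transform$R) * 180 / pi,
    translation_norm = sqrt(sum(x$transform$T^2))
  )
}

#' @describeIn register_meshes ICP iteration history of the report.
#' @export
tidy.registration_report <- function(x, ...) tidy(x$icp)

#' @describeIn register_meshes Residual-history plot of the report.
#' @param object A `registration_report`.
#' @export
autoplot.registration_report <- function(object, ...) {
  autoplot(object$icp) +
    ggplot2::labs(subtitle = sprintf(
      "coarse %.4f mm -> precise %.4f mm",
      object$coarse_distance, object$precise_distance
    ))
}

#' Write a registration report to JSON
#'
#' Includes both stage transforms, the residual history, feature counts
#' and the coarse/precise mean corresponding-point distances.
#'
#' @param report A `registration_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "registration_report"))
  tr_list <- function(t) list(
    R = lapply(1:3, function(i) t$R[i, ]),
    T = t$T,
    convention = "q = R p + T"
  )
  obj <- list(
    coarse_transform = tr_list(report$coarse_transform),
    final_transform = tr_list(report$transform),
    residual_history = report$icp$residuals,
    iterations = report$icp$iterations,
    converged = report$icp$converged,
    n_reference_features = report$n_reference_features,
    n_target_features = report$n_target_features,
    coarse_mean_distance = report$coarse_distance,
    precise_mean_distance = report$precise_distance,
    parameters = report$parameters
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a feature set
#'
#' Projects the feature points to the x-y plane, coloured by curvature.
#'
#' @param object A `feature_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_set <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = curvature)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("feature points (alpha = %g mm^-2)",
                                  object$alpha),
                  colour = "K (mm^-2)") +
    ggplot2::theme_minimal()
}
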