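# dentalign

Rigid registration of triangle-surface meshes that differ in resolution
and coverage — the situation of computer-aided dental implant planning,
where a cone-beam CT reconstruction (full crown-and-root surface, coarse
sampling) must be fused with an intraoral or plaster-model scan
(crowns only, fine sampling). `dentalign` maps the scan (the **target**)
into the CT frame (the **reference**) with a proper rigid transform
`q = R p + T` (`R` a 3×3 rotation with `det R = +1`, `T` in mm), without
any manually placed markers.

The method is the classic two-phase design:

1. **Curvature features.** Both meshes are welded from STL triangle soup
   and every interior vertex gets the discrete Gaussian curvature by
   angle deficit, `K = (2π − Σⱼ θⱼ) / A`, with `θⱼ` the interior angles
   at the vertex and `A` its one-ring area. Vertices with `K > α`
   (default `α = 0.01 mm⁻²`) are feature points.
2. **Coarse registration.** Three spread-out landmarks are picked among
   the reference's curvature peaks; their correspondents in the target
   are found among curvature-similar feature points under
   rigid-invariance constraints on the landmark triangle — side lengths
   (`|d_mᵢmⱼ − d_nᵢnⱼ| < dist_tol`) and Heron area
   (`|S(m) − S(n)| < area_tol`). Local frames of the matched triples give
   `R = Tₙ Tₘᵀ` and `T = centroid(n) − R·centroid(m)`.
3. **Precise registration (ICP).** Iterative closest point with k-d-tree
   correspondences (unique by default: no reference point matched
   twice), the mean corresponding-point distance
   `r = meanᵢ ‖pᵢ − D(i)‖` as stopping statistic
   (`|r⁽ᵏ⁺¹⁾ − r⁽ᵏ⁾| ≤ μ`), and the SVD least-squares estimator — the
   exact minimizer of `e = Σᵢ ‖Qᵢ − (R Pᵢ + T)‖²` — for each update.
   An optional surface-refinement stage matches points to the closest
   point *on* the reference surface, which matters when the reference is
   much coarser than the target.

Because no clinical mesh pair can ship with the package, a synthetic
phantom generator produces dental-arch-like surface pairs (smooth dome +
Gaussian "cusps", decimated full reference vs dense displaced noisy
crop) with known ground-truth transforms, so every stage is testable
end to end. See the methods vignette
(`vignettes/registration-methods.Rmd`) for the model, parameter choices
and limitations.

## Worked example

```r
library(dentalign)

# a phantom surface and a clinically-shaped mesh pair from it:
# reference = decimated full surface, target = dense noisy crop,
# displaced by a hidden rigid transform (<= 30 deg, <= 20 mm)
ph   <- make_phantom(n_cusps = 4, seed = 7)
pair <- make_pair(ph, rotation_max = 30, translation_max = 20,
                  noise_sd = 0.05, seed = 7)

report <- register_meshes(
  pair$reference, pair$target,
  curv_metric = "quantile", curv_tol = 0.3,   # cross-resolution matching
  max_candidates = 192, dist_tol = 2.5, area_tol = 10,
  refine_full = TRUE
)
report
#> <registration_report>
#>   features: 25 (reference), 572 (target)
#>   coarse mean distance:  0.0511 mm
#>   precise mean distance: 0.0428 mm  (4 ICP iteration(s), converged)
#>   final rotation 10.192 deg, translation 1.919 mm

# how close is the estimate to the hidden truth?
gt <- pair$ground_truth
rotation_angle(crossprod(report$transform$R, gt$R)) * 180 / pi
#> [1] 0.05986316
sqrt(sum((report$transform$T - gt$T)^2))
#> [1] 0.0165935
```

Reading the numbers: the coarse stage already places the crop on the
right cusps (mean corresponding-point distance 0.051 mm against the
reference surface), the ICP refinement drops that to 0.043 mm — the
vertex-noise floor (`mean |N(0, 0.05)| ≈ 0.04 mm`) — and the recovered
pose is 0.06° / 0.017 mm away from the hidden ground truth, far inside
clinical tolerance. The mean-distance improvement from coarse to precise
is the standard accuracy comparison for this two-stage design.

`glance(report)` returns the one-row summary, `tidy(report)` the ICP
residual history, and `autoplot(report)` the convergence plot. For
same-resolution problems (e.g. aligning a mesh with a rigidly moved copy
of itself) the defaults — absolute curvature matching with
`curv_tol = 0.00015 mm⁻²`, `dist_tol = 1 mm`, `area_tol = 1 mm²` — apply.

A thin command-line interface wraps the same functions
(`inst/cli/dentalign.R`): subcommands `features`, `coarse`, `register`,
`synth` (write a phantom pair + ground truth to disk) and `validate`
(check a transform JSON); exit codes distinguish I/O errors (2), coarse
no-match (3) and ICP non-convergence (4).

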