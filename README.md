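# nutrigeom

Differential-geometric characterization of performance landscapes from
geometric-framework (GF) nutrition experiments.

GF experiments feed animals diets that differ in protein intake (`x`)
and carbohydrate intake (`y`) and record one or more performance traits
(`z`): lifespan, egg production, growth. The expected trait value over
the intake plane is the *performance landscape*. Most existing analyses
locate its peaks and valleys; `nutrigeom` instead characterizes the
landscape's global shape:

- **Quadratic landscape model.** Each trait is fitted by ordinary least
  squares as `z = a x² + b y² + c x + d y + e xy + z₀`, and the fit is
  benchmarked against a generalized additive model and a thin-plate
  spline on a seeded 60/40 train/test split with bootstrap resampling
  (`fit_quadratic()`, `compare_models()`).
- **Curvature fields.** Treating the landscape as the Monge patch
  `(x, y) ↦ (x, y, f(x, y))`, the first and second fundamental forms
  give the Gauss curvature `K = (LN − M²)/(EG − F²)` and mean
  curvature `H = (GL − 2FM + EN)/(2(EG − F²))` at every grid point,
  plus principal curvatures (shape-operator eigenvalues) and a
  flat/convex/hyperbolic classification (`fundamental_forms()`,
  `curvature_field()`).
- **Surface-area ratio.** Landscape "wiggliness" as
  `A = ∬ √(1 + fx² + fy²) dx dy / (x_max · y_max)` ≥ 1, the landscape's
  area relative to a flat landscape over the same domain
  (`surface_area()`, `area_ratio()`).
- **Hausdorff distance.** Landscapes compared as 3-D point sets with
  the symmetric Hausdorff metric, nutrient axes min–max standardized
  to `[0,1]²` and the trait axis mean-standardized, with bootstrap 95%
  confidence intervals (`hausdorff_distance()`,
  `hausdorff_bootstrap()`).

Canonical validation surfaces (flat, saddle, sphere, cylinder) and a
rail-and-dilution GF experiment simulator are included
(`canonical_flat()`, `canonical_saddle()`, `sphere_patch()`,
`cylinder_patch()`, `simulate_gf_experiment()`).

## Worked example

Simulate a two-trait GF experiment (six rails from P:C 1:16 to 2:1,
four dilutions, five flies per diet) and run the full pipeline:

```r
library(nutrigeom)

design <- gf_design(
  true_surface = list(
    lifespan   = quadratic_surface(-2e-4, -1e-4, 0.1, 0.08, 2e-4, 20),
    daily_eggs = quadratic_surface(-3e-5, -1e-5, 0.01, 0.02, 1e-4, 2)),
  noise_sd = c(lifespan = 2, daily_eggs = 0.3), seed = 2026)
gf <- simulate_gf_experiment(design)

fit_quadratic(gf, "lifespan")
#> <quadratic_surface> z = -0.0003213 x^2 + -0.0001193 y^2 + 0.1205 x
#>   + 0.08111 y + 0.0001004 xy + 20.16

res <- run_pipeline(gf, n = 101, n_boot = 1000, seed = 2026)
res$area
#>        trait domain_x_max domain_y_max  area flat_area ratio   tol
#> 1   lifespan        185.3          261 48612     48357 1.005 1e-08
#> 2 daily_eggs        185.3          261 48384     48357 1.001 1e-08
res$hausdorff
#>            comparison   d_H  mean      sd lwr95 upr95 n_boot
#> 1       lifespan-flat 0.451 0.448 0.00345 0.439 0.451   1000
#> 2     daily_eggs-flat 0.974 0.970 0.00585 0.957 0.974   1000
#> 3 lifespan-daily_eggs 0.629 0.626 0.00483 0.615 0.629   1000
```

The area ratios say both fitted landscapes are close to flat on the
raw intake scale (gentle slopes over a large domain inflate area
little). The Hausdorff table says the standardized daily-egg landscape
is the furthest from the flat reference (d_H = 0.97), and the two
trait landscapes differ from each other by 0.63 — with tight bootstrap
CIs because the grids are dense.

On the canonical saddle `z = xy`:

```r
saddle <- quadratic_surface(e = 1)
f <- fundamental_forms(saddle, 0, 0)
gauss_curvature(f)        #> -1
mean_curvature(f)         #> 0
area_ratio(saddle, c(1, 1))$ratio   #> 1.28079
```

The origin of the saddle is hyperbolic with principal curvatures
(1, −1); its surface area over the unit square exceeds the flat area
by 28%.

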