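---
title: "Geometry of nutritional performance landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of nutritional performance landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrigeom)
```

## The model

A geometric-framework (GF) experiment records a performance trait $z$
(lifespan, egg production, ...) for animals whose protein intake $x$
and carbohydrate intake $y$ vary across diets. `nutrigeom` models the
expected trait surface — the *performance landscape* — as a quadratic
polynomial fitted by ordinary least squares:

$$z = a x^2 + b y^2 + c x + d y + e\,x y + z_0 .$$

The quadratic family is the lowest-degree polynomial that carries
curvature, and it is closed under differentiation and integration, so
every geometric quantity below has an exact closed form in the fitted
coefficients. Whether a quadratic is *adequate* for a given dataset is
an empirical question: `compare_models()` splits the data 60/40 into
training and testing sets, draws bootstrap resamples of the training
set, and fits the quadratic LM alongside an additive smoother
$z \sim s(x) + s(y)$ and a thin-plate spline $z \sim s(x, y)$ (both
`mgcv::gam` with default smoothness selection). If the quadratic's
test RMSE tracks the smoothers', the closed-form model is not losing
real structure. RMSE is the root-*mean*-square of residuals, so values
are comparable between the differently sized training and testing
sets.

The intercept $z_0$ deserves a note: a trait surface through the
origin is biologically unreasonable (animals on the poorest diet still
have non-zero lifespan), so the regression includes an intercept even
though a constant shifts the landscape rigidly and cancels from every
gradient, curvature and surface-area expression. The test suite
asserts this invariance explicitly.

## Curvature of a Monge patch

The landscape is the Monge patch $(x,y) \mapsto (x, y, f(x,y))$. Its
tangent vectors $(1, 0, f_x)$ and $(0, 1, f_y)$ give the first
fundamental form

$$E = 1 + f_x^2,\quad F = f_x f_y,\quad G = 1 + f_y^2,$$

and, with the unit normal
$\vec n = (-f_x, -f_y, 1)/W$, $W = \sqrt{1 + f_x^2 + f_y^2}$, the
second fundamental form

$$L = f_{xx}/W,\quad M = f_{xy}/W,\quad N = f_{yy}/W ,$$

from which

$$K = \frac{LN - M^2}{EG - F^2}, \qquad
  H = \frac{GL - 2FM + EN}{2(EG - F^2)} .$$

$K$ (units 1/length²) is intrinsic — the product of the principal
curvatures, unchanged by bending without stretching — and its sign
classifies each point as flat, convex (peak-like) or hyperbolic
(pass-like). $H$ (units 1/length) is extrinsic — the mean of the
principal curvatures — and distinguishes shapes that $K$ cannot: a
cylinder has $K = 0$ everywhere like a plane, but $H \neq 0$.
`principal_curvatures()` computes the shape-operator eigenvalues by an
explicit eigendecomposition of $I^{-1} II$, a deliberately independent
route that the tests reconcile with the closed forms to $10^{-9}$.

**Normal orientation.** The cross-product order
$\partial_x \times \partial_y$ fixes the upward normal. Orientation is
a genuine convention: flipping it negates $H$ (and every odd function
of it) while leaving $K$ untouched. Under the upward convention the
saddle $z = xy$ has $H = -xy/(1 + x^2 + y^2)^{3/2}$: negative where
the surface bends upwards (first and third quadrants), positive where
it bends downwards. All signs reported by the package follow this
convention.

**Validation fixtures.** `sphere_patch(r)` and `cylinder_patch(r)`
supply analytic partials for the two canonical curved surfaces
($K = 1/r^2$; $K = 0$ with $H \neq 0$). Partials are hand-derived per
fixture rather than produced by automatic differentiation, so the
fixtures remain independent oracles for the curvature code. A
finite-difference route (central differences on the height function
alone) re-derives $K$ and $H$ in the tests to a relative $10^{-4}$.

## Surface area and the wiggliness ratio

The landscape's area over the domain
$\Omega = [0, x_{max}] \times [0, y_{max}]$ is

$$A_S = \iint_\Omega \sqrt{1 + f_x^2 + f_y^2}\; dx\, dy ,$$

and the *surface-area ratio* $A = A_S / (x_{max}\, y_{max}) \ge 1$
compares it with the flat rectangle: 1 means flat, larger means the
trait responds more steeply somewhere in the domain. The integrand is
bounded below by 1, which is what guarantees the ratio's lower bound —
and is also why the square root in the integrand is not optional: on
the flat landscape $z = 1$ the root gives exactly ratio 1 regardless
of the reference height. The trait axis is deliberately kept on its
original scale here; the ratio measures real deviations in $z$.

The ratio depends strongly on the integration domain (for the saddle
$z = xy$ it is 1.28079 over $[0,1]^2$ and grows without bound on
larger squares), so `area_ratio()` always reports the domain used and
the command-line tools require it explicitly.

Numerics: for analytic surfaces, adaptive 2-D quadrature
(`pracma::integral2`) to absolute tolerance `1e-8` (default; exposed),
with an error raised — carrying the achieved estimate — if the
quadrature's error bound exceeds the tolerance. For landscapes known
only as a grid of predictions, a composite-Simpson rule on the grid
with central-difference gradients; with the default 101-node axes the
two routes agree to about $10^{-4}$ on quadratic fixtures, and Simpson
weights fall back to trapezoid on an even node count.

## Hausdorff distance between landscapes

Two landscapes $S_m, S_n$ are compared as finite 3-D point sets over a
*shared* $(x, y)$ grid template:

$$d_H(S_m, S_n) = \max\Big(
   \sup_{p \in S_m} \inf_{q \in S_n} \lVert p - q\rVert,\;
   \sup_{q \in S_n} \inf_{p \in S_m} \lVert p - q\rVert \Big).$$

Both directions matter: in one dimension, $\{1,2\}$ sits inside
$\{1,2,3,4\}$ so the forward directed distance is 0, yet the reverse
is 2, and $d_H = 2$. The symmetric maximum is zero iff the two sets
coincide, making $d_H$ a true metric (the tests verify symmetry,
identity and the triangle inequality against a brute-force double
loop).

Standardization before distancing: the nutrient axes are min–max
standardized to $[0,1]^2$ so that neither intake axis dominates by
units, and each landscape's $z$ is divided by its own mean
(`mean_standardize()`, output mean exactly 1) so traits on different
scales — days versus egg counts — are comparable. Mean-standardization
makes $d_H$ invariant to uniform rescaling of a trait, which is the
point; it also means $d_H$ answers "how different are the landscape
*shapes*", not "how different are the raw values".

The kernel is an exact early-break scan (compiled; bit-identical to
the double loop), so dense grids are cheap: a 101×101 pair costs well
under a second.

**Bootstrap CIs.** `hausdorff_bootstrap()` resamples grid *nodes* with
replacement — the same node indices applied to both landscapes — and
recomputes $d_H$ on each resample (`boot::boot`; percentile 95%
interval; default 1000 resamples). Resampling nodes preserves the
pairing and the shared template; standardization happens once on the
full grids, so the resampled statistic is a pure function of the node
subset. Because a resample can only drop extreme points, the bootstrap
distribution of a supremum-type statistic sits at or below the
full-grid point estimate — both are reported, and the headline `d_H`
is always the full-grid value. The bootstrap unit is a design choice;
resampling animals instead would propagate fitting uncertainty but
break the shared-grid requirement mid-resample.

## The simulator and what it does (not) emulate

`gf_design()` / `simulate_gf_experiment()` emulate the standard GF
layout: diets on *nutritional rails* (fixed P:C ratios) at several
dilutions, several animals per diet. Defaults — six rails from 1:16 to
2:1, four total-intake levels 30–240 (arbitrary intake units), five
replicates, multiplicative log-normal intake jitter with sd 0.1 —
were chosen once as a realistic desk-scale fly design; they give 120
animals whose realized intakes scatter around the rails the way ad
libitum feeding does. Traits are generated as a true quadratic surface
plus i.i.d. Gaussian noise.

What this does *not* emulate: trait-dependent (heteroscedastic or
non-Gaussian) noise, censoring in lifespan assays, correlated traits
within an animal, or landscapes that are genuinely non-quadratic.
Passing tests on simulated data therefore demonstrate that the
*pipeline* recovers what it assumes — a quadratic truth under additive
noise — not that any real landscape is quadratic; that question is
what `compare_models()` asks of each empirical dataset. The full
empirical application of this pipeline requires the archived fly
dataset (lifespan, lifetime and daily egg production), which must be
downloaded separately; every run on it should record the grid
resolution and bootstrap settings alongside the results, which is what
the pipeline manifest does.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| grid nodes per axis `n` | 101 | — | both endpoints included; all traits share one template; area/Hausdorff reports depend on it and record it |
| quadrature tolerance | `1e-8` | absolute, units of $x\,y$ | adaptive route only |
| zero-curvature tolerance | `1e-8` | units of $K$ | classification only; sized for min–max standardized domains, raise it on raw intake scales |
| train/test split | 0.6 | fraction | uniform, unstratified |
| model-comparison resamples | 200 | — | tests use 5–25 for speed |
| Hausdorff bootstrap resamples | 1000 | — | percentile 95% CI |
| intake jitter sd | 0.1 | log scale | 0 puts diets exactly on rails |

Every stochastic entry point (`simulate_gf_experiment()`,
`compare_models()`, `hausdorff_bootstrap()`, `run_pipeline()`)
requires an explicit seed and is bitwise reproducible given one; the
pipeline writes the seed and every tolerance into `manifest.json`.

## Degenerate inputs and tie-breaks

- Constant vectors cannot be min–max standardized, zero-mean vectors
  cannot be mean-standardized; both raise "degenerate scale" errors
  rather than returning NaN.
- A design with all diets on one rail is collinear in the quadratic
  basis; `fit_quadratic()` names the collinear columns. Fewer than 6
  records is rejected outright.
- `classify_point()` breaks the flat/curved tie with `|K| <= tol`
  counting as flat, so numerically-zero curvature from a fitted
  near-plane classifies as flat instead of flickering by sign.
- Principal curvatures are returned sorted $\kappa_1 \ge \kappa_2$.
- Grids with mismatched $(x,y)$ templates are refused by the Hausdorff
  functions with instructions to re-grid, never silently interpolated.

## Problem sizes

The shipped test-suite and acceptance computations run on grids of
11–101 nodes per axis, point sets up to 500 points for brute-force
comparisons, 1000 random points for the eigenvalue reconciliation,
Monte-Carlo recovery over 50 replicates of 120 simulated animals, and
20–50 bootstrap resamples inside tests (1000 in the documented
defaults). These sizes were chosen so the full suite completes in
well under a minute while every property is still exercised at a
scale where failure modes (rank deficiency, tie-breaking, resampling
degeneracy) actually appear.

## Known limitations

- Two nutrient axes only; the fundamental-form machinery is specific
  to surfaces in $\mathbb{R}^3$, and no $n$-dimensional generalization
  is attempted because the closed forms used here do not carry over
  verbatim.
- The quadratic model cannot represent multi-peaked landscapes;
  `compare_models()` will show the smoothers winning when that
  matters.
- Surface-area ratios on raw intake scales mix trait units with intake
  units inside the integrand; ratios are comparable between traits
  only over a common domain and trait scale, which is why the
  Hausdorff comparison (fully standardized) is the cross-trait metric
  of choice.
- The bootstrap CI reflects grid-resampling variability, not
  experimental sampling error in the fitted coefficients.
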