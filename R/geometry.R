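#' Gradient of a landscape
#'
#' First partial derivatives \eqn{(f_x, f_y)} of the height function
#' at one or more points. For a [quadratic_surface()] these are the
#' closed forms \eqn{f_x = 2ax + c + ey}, \eqn{f_y = 2by + d + ex}.
#'
#' @param surface a [surface_patch()].
#' @param x,y point coordinates; vectors are recycled to a common
#'   length.
#' @return A numeric matrix with one row per point and columns
#'   `fx`, `fy`.
#' @examples
#' gradient(quadratic_surface(e = 1), 2, 3)   # saddle: (y, x) = (3, 2)
#' @export
gradient <- function(surface, x, y) {
  stopifnot(inherits(surface, "surface_patch"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("point coordinates must be finite")
  cbind(fx = surface$dx(x, y), fy = surface$dy(x, y))
}

#' Upward unit normal of a landscape
#'
#' Normalized cross product of the tangent vectors \eqn{(1, 0, f_x)}
#' and \eqn{(0, 1, f_y)}, in that order, giving
#' \eqn{(-f_x, -f_y, 1)/\sqrt{1 + f_x^2 + f_y^2}}: the normal with a
#' positive vertical component. Flipping the orientation would negate
#' the mean curvature everywhere and leave the Gauss curvature
#' unchanged; the upward convention makes the mean curvature of the
#' saddle `z = xy` negative where the surface bends upwards (first
#' and third quadrants) and positive where it bends downwards.
#'
#' @inheritParams gradient
#' @return A numeric matrix with one row per point and columns
#'   `nx`, `ny`, `nz`; each row has unit Euclidean norm.
#' @examples
#' unit_normal(quadratic_surface(), 0.2, 0.9)  # flat: (0, 0, 1)
#' @export
unit_normal <- function(surface, x, y) {
  g <- gradient(surface, x, y)
  if (!all(is.finite(g))) stop("non-finite partial derivatives at the point")
  fx <- unname(g[, "fx"]); fy <- unname(g[, "fy"])
  w <- sqrt(1 + fx^2 + fy^2)
  cbind(nx = -fx / w, ny = -fy / w, nz = 1 / w)
}

#' First and second fundamental forms of a Monge patch
#'
#' The metric (first form) entries are dot products of the tangent
#' vectors: \eqn{E = 1 + f_x^2}, \eqn{F = f_x f_y},
#' \eqn{G = 1 + f_y^2}. The bending (second form) entries are dot
#' products of the second-partial vectors \eqn{(0, 0, f_{..})} with
#' the unit normal, so \eqn{L = f_{xx}/W}, \eqn{M = f_{xy}/W},
#' \eqn{N = f_{yy}/W} with \eqn{W = \sqrt{1 + f_x^2 + f_y^2}}.
#' For a Monge patch \eqn{EG - F^2 = W^2 \ge 1}: the metric is never
#' degenerate.
#'
#' @inheritParams gradient
#' @return An object of class `fundamental_forms`: a list with numeric
#'   vectors `E`, `F`, `G`, `L`, `M`, `N` (one entry per point), the
#'   `normal` matrix, and the evaluation coordinates `x`, `y`.
#' @examples
#' fundamental_forms(quadratic_surface(e = 1), 1, 1)  # saddle at (1,1)
#' @export
fundamental_forms <- function(surface, x, y) {
  g <- gradient(surface, x, y)
  fx <- unname(g[, "fx"]); fy <- unname(g[, "fy"])
  n <- length(fx)
  xr <- rep_len(as.numeric(x), n); yr <- rep_len(as.numeric(y), n)
  fxx <- surface$dxx(xr, yr); fyy <- surface$dyy(xr, yr)
  fxy <- surface$dxy(xr, yr)
  if (!all(is.finite(c(fx, fy, fxx, fyy, fxy))))
    stop("non-finite partial derivatives at the point")
  w <- sqrt(1 + fx^2 + fy^2)
  structure(
    list(E = 1 + fx^2, F = fx * fy, G = 1 + fy^2,
         L = fxx / w, M = fxy / w, N = fyy / w,
         normal = cbind(nx = -fx / w, ny = -fy / w, nz = 1 / w),
         x = xr, y = yr),
    class = "fundamental_forms"
  )
}

#' @export
print.fundamental_forms <- function(x, ...) {
  cat("<fundamental_forms> at", length(x$E), "point(s)\n")
  print(data.frame(E = x$E, F = x$F, G = x$G,
                   L = x$L, M = x$M, N = x$N)[seq_len(min(6, length(x$E))), ])
  invisible(x)
}

.check_forms <- function(forms) {
  stopifnot(inherits(forms, "fundamental_forms"))
  det1 <- forms$E * forms$G - forms$F^2
  if (any(det1 <= 0))
    stop("degenerate first fundamental form (EG - F^2 <= 0); ",
         "cannot occur for a Monge patch")
  det1
}

#' Gauss curvature from the fundamental forms
#'
#' \deqn{K = \frac{LN - M^2}{EG - F^2}.}
#' The intrinsic curvature: the product of the principal curvatures,
#' invariant under bending without stretching. Its sign classifies a
#' point as flat (0), convex (> 0) or hyperbolic (< 0).
#'
#' @param forms a [fundamental_forms()] object.
#' @return Numeric vector of Gauss curvatures, one per point
#'   (units 1/length^2).
#' @examples
#' gauss_curvature(fundamental_forms(quadratic_surface(e = 1), 0, 0))  # -1
#' @export
gauss_curvature <- function(forms) {
  det1 <- .check_forms(forms)
  (forms$L * forms$N - forms$M^2) / det1
}

#' Mean curvature from the fundamental forms
#'
#' \deqn{H = \frac{GL - 2FM + EN}{2(EG - F^2)}.}
#' The extrinsic curvature: the arithmetic mean of the principal
#' curvatures. Under the upward-normal convention of [unit_normal()],
#' `H` is negative where the landscape bends upwards and positive
#' where it bends downwards (for the saddle `z = xy`:
#' \eqn{H = -xy / (1 + x^2 + y^2)^{3/2}}).
#'
#' @inheritParams gauss_curvature
#' @return Numeric vector of mean curvatures (units 1/length).
#' @examples
#' mean_curvature(fundamental_forms(cylinder_patch(1), 0, 0))  # -1/2
#' @export
mean_curvature <- function(forms) {
  det1 <- .check_forms(forms)
  (forms$G * forms$L - 2 * forms$F * forms$M + forms$E * forms$N) / (2 * det1)
}

#' Principal curvatures via the shape operator
#'
#' The principal curvatures are the eigenvalues of the shape operator
#' \eqn{I^{-1} II}, the linear map encoding how much the surface bends
#' in each tangent direction. The operator is self-adjoint with
#' respect to the metric, so both eigenvalues are real; they satisfy
#' \eqn{\kappa_1 \kappa_2 = K} and \eqn{(\kappa_1 + \kappa_2)/2 = H}.
#' This route is computed by explicit eigendecomposition, independent
#' of the closed-form [gauss_curvature()] / [mean_curvature()]
#' expressions.
#'
#' @inheritParams gauss_curvature
#' @return A numeric matrix with one row per point and columns
#'   `k1`, `k2`, sorted so `k1 >= k2`.
#' @examples
#' principal_curvatures(fundamental_forms(quadratic_surface(e = 1), 0, 0))
#' @export
principal_curvatures <- function(forms) {
  .check_forms(forms)
  n <- length(forms$E)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("k1", "k2")))
  for (i in seq_len(n)) {
    I  <- matrix(c(forms$E[i], forms$F[i], forms$F[i], forms$G[i]), 2, 2)
    II <- matrix(c(forms$L[i], forms$M[i], forms$M[i], forms$N[i]), 2, 2)
    ev <- eigen(solve(I, II), only.values = TRUE)$values
    if (is.complex(ev)) {
      if (max(abs(Im(ev))) > 1e-8 * max(1, abs(ev)))
        stop("shape operator returned non-real eigenvalues")
      ev <- Re(ev)
    }
    out[i, ] <- sort(ev, decreasing = TRUE)
  }
  out
}

#' Classify a point by the sign of its Gauss curvature
#'
#' Points with `|K| <= tol` are flat, `K > tol` convex (peak-like:
#' triangles drawn on the surface have angle sums above pi), and
#' `K < -tol` hyperbolic (mountain-pass-like; angle sums below pi).
#'
#' @param K numeric vector of Gauss curvatures.
#' @param tol non-negative tolerance below which curvature counts as
#'   zero. The default `1e-8` suits landscapes on min-max standardized
#'   domains; it is exposed because raw intake units change the scale
#'   of `K`.
#' @return Character vector with values `"flat"`, `"convex"` or
#'   `"hyperbolic"`.
#' @examples
#' classify_point(c(0, 0.5, -1))
#' @export
classify_point <- function(K, tol = 1e-8) {
  stopifnot(is.numeric(tol), length(tol) == 1, tol > 0)
  if (!all(is.finite(K))) stop("non-finite Gauss curvature")
  ifelse(abs(K) <= tol, "flat", ifelse(K > 0, "convex", "hyperbolic"))
}

#' Curvature field of a landscape over a prediction grid
#'
#' Evaluates Gauss curvature, mean curvature and the sign-based region
#' class at every node of a [landscape_grid()]. When `surface` is
#' omitted and the grid carries quadratic-fit provenance, the fitted
#' surface is reconstructed from the stored coefficients.
#'
#' @param surface a [surface_patch()]; may be `NULL` for grids built
#'   by [predict_grid()], which remember their surface.
#' @param grid a [landscape_grid()].
#' @param tol zero-curvature classification tolerance, see
#'   [classify_point()].
#' @return A `curvature_field`: a data frame with columns `x`, `y`,
#'   `z`, `K`, `H`, `region_class`, one row per grid node (row-major:
#'   `x` varies fastest).
#' @examples
#' g <- canonical_saddle(n = 21)
#' cf <- curvature_field(grid = g)
#' cf[cf$x == 0 & cf$y == 0, ]    # K = -1, H = 0
#' @export
curvature_field <- function(surface = NULL, grid, tol = 1e-8) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (is.null(surface)) surface <- grid$surface
  if (is.null(surface))
    stop("no surface supplied and the grid carries no fitted surface")
  if (length(grid$x) == 0 || length(grid$y) == 0) stop("empty grid")
  pts <- expand.grid(x = grid$x, y = grid$y, KEEP.OUT.ATTRS = FALSE)
  forms <- fundamental_forms(surface, pts$x, pts$y)
  K <- gauss_curvature(forms)
  H <- mean_curvature(forms)
  out <- data.frame(x = pts$x, y = pts$y, z = as.vector(grid$z),
                    K = K, H = H,
                    region_class = classify_point(K, tol),
                    stringsAsFactors = FALSE)
  attr(out, "tol") <- tol
  attr(out, "trait") <- grid$trait
  class(out) <- c("curvature_field", class(out))
  out
}
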