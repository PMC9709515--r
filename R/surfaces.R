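#' Surface patches: height functions over the nutrient plane
#'
#' A performance landscape is treated as a Monge patch
#' \eqn{(x, y) \mapsto (x, y, f(x, y))}: a surface given by a height
#' function over the (protein, carbohydrate) intake plane. A
#' `surface_patch` bundles the height function together with its first
#' and second partial derivatives, all supplied analytically so that
#' curvature computations are closed-form. All six functions must be
#' vectorized in `(x, y)`.
#'
#' @param height function of `(x, y)` returning the trait value `z`.
#' @param dx,dy functions of `(x, y)` returning the first partials
#'   \eqn{f_x}, \eqn{f_y}.
#' @param dxx,dyy,dxy functions of `(x, y)` returning the second
#'   partials \eqn{f_{xx}}, \eqn{f_{yy}} and the (symmetric) mixed
#'   partial \eqn{f_{xy}}.
#' @param name optional label used in printing.
#' @return An object of class `surface_patch`: a list with elements
#'   `height`, `dx`, `dy`, `dxx`, `dyy`, `dxy`, `name`.
#' @seealso [quadratic_surface()], [sphere_patch()], [cylinder_patch()]
#' @examples
#' # an inclined plane z = x
#' p <- surface_patch(function(x, y) x,
#'                    dx = function(x, y) rep(1, length(x)),
#'                    dy = function(x, y) rep(0, length(x)),
#'                    dxx = function(x, y) rep(0, length(x)),
#'                    dyy = function(x, y) rep(0, length(x)),
#'                    dxy = function(x, y) rep(0, length(x)))
#' gradient(p, 0.3, 0.7)
#' @export
surface_patch <- function(height, dx, dy, dxx, dyy, dxy, name = "surface") {
  funs <- list(height = height, dx = dx, dy = dy,
               dxx = dxx, dyy = dyy, dxy = dxy)
  ok <- vapply(funs, is.function, logical(1))
  if (!all(ok)) {
    stop("surface_patch components must all be functions; not functions: ",
         paste(names(funs)[!ok], collapse = ", "))
  }
  structure(c(funs, list(name = name)), class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat("<surface_patch>", x$name, "\n")
  invisible(x)
}

#' Quadratic performance landscape
#'
#' The landscape model underlying GF response-surface analysis:
#' \deqn{z = a x^2 + b y^2 + c x + d y + e x y + z_0,}
#' the quadratic polynomial fitted to trait data by
#' [fit_quadratic()]. The intercept \eqn{z_0} shifts the height only
#' and never enters any gradient, curvature or surface-area
#' expression.
#'
#' @param a,b,c,d,e real coefficients of the quadratic polynomial.
#' @param intercept constant height offset \eqn{z_0} (default 0).
#' @return A `quadratic_surface`, which is also a [surface_patch()]
#'   with exact analytic partials: \eqn{f_x = 2ax + c + ey},
#'   \eqn{f_y = 2by + d + ex}, \eqn{f_{xx} = 2a}, \eqn{f_{yy} = 2b},
#'   \eqn{f_{xy} = e}. Coefficients are kept in `$coefficients`.
#' @examples
#' s <- quadratic_surface(e = 1)     # the canonical saddle z = xy
#' s$height(2, 3)
#' gradient(s, 2, 3)
#' @export
quadratic_surface <- function(a = 0, b = 0, c = 0, d = 0, e = 0,
                              intercept = 0) {
  cf <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
          e = unname(e), intercept = unname(intercept))
  if (length(cf) != 6 || !all(is.finite(cf)))
    stop("coefficients must be finite scalars")
  force(cf)
  p <- surface_patch(
    height = function(x, y)
      cf[["a"]] * x^2 + cf[["b"]] * y^2 + cf[["c"]] * x + cf[["d"]] * y +
        cf[["e"]] * x * y + cf[["intercept"]],
    dx  = function(x, y) 2 * cf[["a"]] * x + cf[["c"]] + cf[["e"]] * y,
    dy  = function(x, y) 2 * cf[["b"]] * y + cf[["d"]] + cf[["e"]] * x,
    dxx = function(x, y) rep_len(2 * cf[["a"]], length(x)),
    dyy = function(x, y) rep_len(2 * cf[["b"]], length(x)),
    dxy = function(x, y) rep_len(cf[["e"]], length(x)),
    name = "quadratic"
  )
  p$coefficients <- cf
  class(p) <- c("quadratic_surface", class(p))
  p
}

#' @export
print.quadratic_surface <- function(x, ...) {
  cf <- x$coefficients
  cat("<quadratic_surface> z = ",
      sprintf("%.4g x^2 + %.4g y^2 + %.4g x + %.4g y + %.4g xy + %.4g",
              cf["a"], cf["b"], cf["c"], cf["d"], cf["e"], cf["intercept"]),
      "\n", sep = "")
  if (!is.null(x$trait)) cat("  trait:", x$trait, "\n")
  invisible(x)
}

#' Canonical curved validation surfaces
#'
#' Analytic sphere and cylinder caps used to validate the curvature
#' machinery. A sphere of radius `r` has Gauss curvature \eqn{1/r^2}
#' everywhere; a cylinder of radius `r` has Gauss curvature 0 (it is a
#' plane bent without stretching) but non-zero mean curvature, which
#' is what distinguishes it from a genuinely flat landscape.
#'
#' @param r radius (> 0). The sphere patch `z = sqrt(r^2 - x^2 - y^2)`
#'   is valid for `x^2 + y^2 < r^2`; the cylinder patch
#'   `z = sqrt(r^2 - x^2)` for `|x| < r`.
#' @return A [surface_patch()] with analytic partials.
#' @examples
#' s <- sphere_patch(2)
#' gauss_curvature(fundamental_forms(s, 0.1, 0.2))  # 1/4
#' @export
sphere_patch <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1, is.finite(r), r > 0)
  h <- function(x, y) sqrt(r^2 - x^2 - y^2)
  surface_patch(
    height = h,
    dx  = function(x, y) -x / h(x, y),
    dy  = function(x, y) -y / h(x, y),
    dxx = function(x, y) -(r^2 - y^2) / h(x, y)^3,
    dyy = function(x, y) -(r^2 - x^2) / h(x, y)^3,
    dxy = function(x, y) -x * y / h(x, y)^3,
    name = sprintf("sphere r=%g", r)
  )
}

#' @rdname sphere_patch
#' @examples
#' cyl <- cylinder_patch(1)
#' forms <- fundamental_forms(cyl, 0, 0.5)
#' c(K = gauss_curvature(forms), H = mean_curvature(forms))
#' @export
cylinder_patch <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1, is.finite(r), r > 0)
  h <- function(x) sqrt(r^2 - x^2)
  surface_patch(
    height = function(x, y) rep_len(h(x), max(length(x), length(y))),
    dx  = function(x, y) -x / h(x),
    dy  = function(x, y) rep_len(0, max(length(x), length(y))),
    dxx = function(x, y) -r^2 / h(x)^3,
    dyy = function(x, y) rep_len(0, max(length(x), length(y))),
    dxy = function(x, y) rep_len(0, max(length(x), length(y))),
    name = sprintf("cylinder r=%g", r)
  )
}
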