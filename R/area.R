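#' Surface area of a performance landscape
#'
#' The area of the graph of `f` over the rectangle
#' `[0, x_max] x [0, y_max]`:
#' \deqn{A_S = \int_0^{y_{max}}\!\!\int_0^{x_{max}}
#'   \sqrt{1 + f_x^2 + f_y^2}\; dx\, dy.}
#' For an analytic [surface_patch()] the integral is evaluated by
#' adaptive 2-D quadrature ([pracma::integral2()]); for a
#' [landscape_grid()] (where only node heights are known) by composite
#' Simpson integration of the same integrand with the gradient taken
#' by central finite differences on the grid.
#'
#' @param surface a [surface_patch()] or a [landscape_grid()].
#' @param domain integration rectangle as a [nutrient_domain()] or
#'   `c(x_max, y_max)`; for a grid the grid's own domain is used and
#'   `domain` must be omitted.
#' @param tol absolute quadrature tolerance (default `1e-8`; analytic
#'   route only).
#' @param ... unused.
#' @return The surface area (units of `x * y`), with attribute
#'   `"error"` carrying the quadrature error estimate where available.
#' @examples
#' surface_area(quadratic_surface(intercept = 1), c(1, 1))   # flat: 1
#' surface_area(quadratic_surface(e = 1), c(1, 1))           # saddle: 1.28079
#' @export
surface_area <- function(surface, domain, tol = 1e-8, ...) {
  UseMethod("surface_area")
}

#' @export
surface_area.surface_patch <- function(surface, domain, tol = 1e-8, ...) {
  domain <- .as_domain(domain)
  stopifnot(is.numeric(tol), length(tol) == 1, tol > 0)
  integrand <- function(x, y)
    sqrt(1 + surface$dx(x, y)^2 + surface$dy(x, y)^2)
  q <- pracma::integral2(integrand, 0, domain[["x_max"]],
                         0, domain[["y_max"]],
                         reltol = tol, abstol = tol)
  if (!is.finite(q$Q))
    stop("quadrature failed: non-finite surface area")
  if (q$error > max(tol, tol * abs(q$Q)))
    stop(sprintf(paste0("quadrature did not reach tolerance %g: ",
                        "estimate %.10g with error bound %.3g"),
                 tol, q$Q, q$error))
  structure(q$Q, error = q$error)
}

#' @export
surface_area.landscape_grid <- function(surface, domain, tol = 1e-8, ...) {
  grid <- surface
  if (!missing(domain) && !is.null(domain)) {
    domain <- .as_domain(domain)
    if (!isTRUE(all.equal(unclass(domain),
                          c(x_max = max(grid$x), y_max = max(grid$y)))))
      stop("a landscape_grid is integrated over its own domain; ",
           "re-grid the surface instead of overriding the domain")
  }
  hx <- diff(grid$x[1:2]); hy <- diff(grid$y[1:2])
  g <- pracma::gradient(t(grid$z), hx, hy)   # rows of t(z) index y
  integrand <- sqrt(1 + t(g$X)^2 + t(g$Y)^2)
  .simpson2d(integrand, hx, hy)
}

# composite Simpson weights on an equispaced grid (odd node count per
# axis); falls back to trapezoid on any axis with an even count
.simpson_w <- function(n, h) {
  if (n < 2) stop("need at least 2 nodes per axis")
  if (n %% 2 == 1) {
    w <- rep(c(2, 4), length.out = n)
    w[1] <- 1; w[n] <- 1
    w * h / 3
  } else {
    w <- rep(1, n); w[c(1, n)] <- 0.5
    w * h
  }
}

.simpson2d <- function(fmat, hx, hy) {
  wx <- .simpson_w(nrow(fmat), hx)
  wy <- .simpson_w(ncol(fmat), hy)
  as.numeric(wx %*% fmat %*% wy)
}

#' Surface-area ratio against the flat landscape
#'
#' The landscape's surface area divided by the area of the flat
#' rectangle with the same domain (`x_max * y_max`): a dimensionless
#' 'wiggliness' index in `[1, Inf)`. A ratio of 1 means the landscape
#' is flat; larger ratios mean small changes in nutrient balance move
#' the trait more. The trait axis is kept on its original scale so
#' that the ratio reflects real deviations in `z`.
#'
#' @inheritParams surface_area
#' @return A `surface_area_result`: list with `area`, `flat_area`,
#'   `ratio`, `domain`, `tol`.
#' @examples
#' area_ratio(canonical_flat(n = 21))$ratio      # exactly 1
#' area_ratio(quadratic_surface(e = 1), c(1, 1))$ratio
#' @export
area_ratio <- function(surface, domain, tol = 1e-8, ...) {
  if (inherits(surface, "landscape_grid")) {
    a <- surface_area(surface, tol = tol)
    domain <- nutrient_domain(max(surface$x), max(surface$y))
  } else {
    domain <- .as_domain(domain)
    a <- surface_area(surface, domain, tol = tol)
  }
  flat <- domain[["x_max"]] * domain[["y_max"]]
  ratio <- as.numeric(a) / flat
  if (ratio < 1 - 1e-9)
    stop("internal inconsistency: area ratio ", ratio, " below 1")
  structure(
    list(area = as.numeric(a), flat_area = flat, ratio = ratio,
         domain = domain, tol = tol,
         trait = if (inherits(surface, "landscape_grid")) surface$trait
                 else surface$trait %||% surface$name),
    class = "surface_area_result"
  )
}

#' @export
print.surface_area_result <- function(x, ...) {
  cat(sprintf(paste0("<surface_area_result> '%s'\n",
                     "  domain [0, %g] x [0, %g]\n",
                     "  area %.6g, flat area %.6g, ratio %.6g\n"),
              x$trait, x$domain[["x_max"]], x$domain[["y_max"]],
              x$area, x$flat_area, x$ratio))
  invisible(x)
}
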