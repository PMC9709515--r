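# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: finite differences instead of analytic partials,
# a plain double loop instead of the compiled Hausdorff kernel, a midpoint
# Riemann sum instead of adaptive quadrature.

# central finite differences of a height function
fd_gradient <- function(height, x, y, h = 1e-6) {
  c(fx = (height(x + h, y) - height(x - h, y)) / (2 * h),
    fy = (height(x, y + h) - height(x, y - h)) / (2 * h))
}

fd_hessian <- function(height, x, y, h = 1e-4) {
  c(fxx = (height(x + h, y) - 2 * height(x, y) + height(x - h, y)) / h^2,
    fyy = (height(x, y + h) - 2 * height(x, y) + height(x, y - h)) / h^2,
    fxy = (height(x + h, y + h) - height(x + h, y - h) -
             height(x - h, y + h) + height(x - h, y - h)) / (4 * h^2))
}

# Gauss/mean curvature of a Monge patch from finite-difference partials only
fd_curvatures <- function(height, x, y) {
  g <- fd_gradient(height, x, y)
  hss <- fd_hessian(height, x, y)
  w2 <- 1 + g["fx"]^2 + g["fy"]^2
  K <- (hss["fxx"] * hss["fyy"] - hss["fxy"]^2) / w2^2
  H <- ((1 + g["fy"]^2) * hss["fxx"] - 2 * g["fx"] * g["fy"] * hss["fxy"] +
          (1 + g["fx"]^2) * hss["fyy"]) / (2 * w2^1.5)
  c(K = unname(K), H = unname(H))
}

# O(|A||B|) brute-force directed Hausdorff in plain R
brute_directed_hausdorff <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, ncol = 1)
  if (is.null(dim(B))) B <- matrix(B, ncol = 1)
  mins <- apply(A, 1, function(a)
    min(sqrt(colSums((t(B) - a)^2))))
  max(mins)
}

brute_hausdorff <- function(A, B) {
  max(brute_directed_hausdorff(A, B), brute_directed_hausdorff(B, A))
}

# midpoint Riemann sum of the surface-area integrand over [0,xm] x [0,ym]
riemann_area <- function(dxf, dyf, x_max = 1, y_max = 1, cells = 2000) {
  hx <- x_max / cells; hy <- y_max / cells
  xm <- seq(hx / 2, x_max - hx / 2, length.out = cells)
  ym <- seq(hy / 2, y_max - hy / 2, length.out = cells)
  fx <- outer(xm, ym, dxf); fy <- outer(xm, ym, dyf)
  sum(sqrt(1 + fx^2 + fy^2)) * hx * hy
}

# random quadratic surface with coefficients in [-2, 2]
random_quadratic <- function() {
  cf <- stats::runif(6, -2, 2)
  quadratic_surface(cf[1], cf[2], cf[3], cf[4], cf[5], cf[6])
}

# small default simulation design used by fitting/pipeline tests
test_design <- function(noise_sd = 2, seed = 101,
                        traits = list(
                          lifespan = quadratic_surface(-2e-4, -1e-4, 0.1,
                                                       0.08, 2e-4, 20),
                          eggs = quadratic_surface(-1e-4, -2e-4, 0.05,
                                                   0.12, -1e-4, 35))) {
  gf_design(true_surface = traits,
            noise_sd = setNames(rep(noise_sd, length(traits)), names(traits)),
            seed = seed)
}
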