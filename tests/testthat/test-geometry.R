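saddle <- quadratic_surface(e = 1)
flat <- quadratic_surface(intercept = 1)

test_that("unit normal is the upward-normalized cross product of tangents", {
  expect_equal(unname(unit_normal(flat, 0.3, 0.9)[1, ]), c(0, 0, 1))
  expect_equal(unname(unit_normal(saddle, 0, 0)[1, ]), c(0, 0, 1))
  # saddle at (1,0): tangents (1,0,0) x (0,1,1) = (0,-1,1), normalized
  expect_equal(unname(unit_normal(saddle, 1, 0)[1, ]), c(0, -1, 1) / sqrt(2))
  # norm 1 at random points of a random surface
  set.seed(1)
  s <- random_quadratic()
  n <- unit_normal(s, runif(50, -2, 2), runif(50, -2, 2))
  expect_equal(sqrt(rowSums(n^2)), rep(1, 50), tolerance = 1e-12)
})

test_that("fundamental forms match hand-computed values and invariants", {
  f <- fundamental_forms(flat, 0.2, 0.7)
  expect_equal(c(f$E, f$F, f$G, f$L, f$M, f$N), c(1, 0, 1, 0, 0, 0))
  f0 <- fundamental_forms(saddle, 0, 0)
  expect_equal(c(f0$E, f0$F, f0$G, f0$L, f0$M, f0$N), c(1, 0, 1, 0, 1, 0))
  f1 <- fundamental_forms(saddle, 1, 1)
  expect_equal(c(f1$E, f1$F, f1$G, f1$L, f1$M, f1$N),
               c(2, 1, 2, 0, 1 / sqrt(3), 0))
  # EG - F^2 = 1 + fx^2 + fy^2 >= 1, E >= 1, G >= 1 for random surfaces
  set.seed(2)
  for (i in 1:5) {
    s <- random_quadratic()
    fr <- fundamental_forms(s, runif(100, -2, 2), runif(100, -2, 2))
    expect_true(all(fr$E >= 1) && all(fr$G >= 1))
    g <- gradient(s, fr$x, fr$y)
    expect_equal(fr$E * fr$G - fr$F^2, 1 + g[, "fx"]^2 + g[, "fy"]^2)
  }
})

test_that("Gauss and mean curvature reproduce the canonical values", {
  f <- fundamental_forms(flat, 0.5, 0.5)
  expect_identical(gauss_curvature(f), 0)
  expect_identical(mean_curvature(f), 0)
  f0 <- fundamental_forms(saddle, 0, 0)
  expect_equal(gauss_curvature(f0), -1)
  expect_equal(mean_curvature(f0), 0)
  expect_equal(unname(principal_curvatures(f0)[1, ]), c(1, -1))
  # sphere: K = 1/r^2 anywhere on the patch, H = -1/r at the apex
  for (r in c(0.5, 2, 10)) {
    fs <- fundamental_forms(sphere_patch(r), 0.1 * r, 0.2 * r)
    expect_equal(gauss_curvature(fs), 1 / r^2)
    fa <- fundamental_forms(sphere_patch(r), 0, 0)
    expect_equal(mean_curvature(fa), -1 / r)
  }
})

test_that("cylinder has zero Gauss but non-zero mean curvature (Theorema Egregium)", {
  r <- 3
  fc <- fundamental_forms(cylinder_patch(r), c(0, 0.5, -1, 2), c(0, 1, 5, -2))
  expect_equal(gauss_curvature(fc), rep(0, 4))
  expect_true(all(abs(mean_curvature(fc)) > 1e-3))
  # at the crest x = 0 the closed form is -1/(2r)
  expect_equal(mean_curvature(fundamental_forms(cylinder_patch(r), 0, 4)),
               -1 / (2 * r))
})

test_that("principal-curvature eigen route agrees with closed-form K and H", {
  set.seed(42)
  for (i in 1:10) {
    s <- random_quadratic()
    f <- fundamental_forms(s, runif(100, -2, 2), runif(100, -2, 2))
    pc <- principal_curvatures(f)
    expect_equal(pc[, "k1"] * pc[, "k2"], gauss_curvature(f),
                 tolerance = 1e-9)
    expect_equal((pc[, "k1"] + pc[, "k2"]) / 2, mean_curvature(f),
                 tolerance = 1e-9)
    expect_true(all(pc[, "k1"] >= pc[, "k2"]))
  }
})

test_that("closed-form curvatures agree with a finite-difference oracle", {
  fixtures <- list(quadratic_surface(1, -0.5, 0.3, 0.2, 0.8, 2),
                   sphere_patch(2), cylinder_patch(3), saddle)
  pts <- list(c(0.3, 0.4), c(0.1, -0.2), c(0.25, 0.25))
  for (s in fixtures) {
    for (p in pts) {
      f <- fundamental_forms(s, p[1], p[2])
      oracle <- fd_curvatures(s$height, p[1], p[2])
      expect_equal(gauss_curvature(f), oracle[["K"]], tolerance = 1e-4)
      expect_equal(mean_curvature(f), oracle[["H"]], tolerance = 1e-4)
    }
  }
})

test_that("classification follows the sign of K under the tolerance", {
  expect_identical(classify_point(0), "flat")
  expect_identical(classify_point(0.5), "convex")
  expect_identical(classify_point(-1), "hyperbolic")
  expect_identical(classify_point(c(1e-9, 1e-7, -1e-7), tol = 1e-8),
                   c("flat", "convex", "hyperbolic"))
  expect_error(classify_point(NaN), "finite")
  expect_error(classify_point(0, tol = -1))
})

test_that("curvature_field covers the grid and shows the saddle sign pattern", {
  g <- predict_grid(flat, c(1, 1), n = 11)
  cf <- curvature_field(grid = g)
  expect_equal(nrow(cf), 121)
  expect_true(all(cf$K == 0) && all(cf$H == 0))
  expect_true(all(cf$region_class == "flat"))

  gs <- predict_grid(saddle, c(1, 1), n = 11, trait = "saddle")
  # symmetric domain so all four quadrants are present
  gs$x <- gs$x - 0.5; gs$y <- gs$y - 0.5
  gs$z <- outer(gs$x, gs$y, saddle$height)
  cfs <- curvature_field(saddle, gs)
  expect_true(all(cfs$K < 0))                    # hyperbolic everywhere
  expect_true(all(cfs$region_class == "hyperbolic"))
  # H = -xy / (1 + x^2 + y^2)^(3/2): negative where xy > 0, positive where xy < 0
  expect_equal(cfs$H, -cfs$x * cfs$y / (1 + cfs$x^2 + cfs$y^2)^1.5)
  expect_true(all(cfs$H[cfs$x * cfs$y > 0] < 0))
  expect_true(all(cfs$H[cfs$x * cfs$y < 0] > 0))
  expect_error(curvature_field(grid = list()), "landscape_grid")
})

test_that("curvature is invariant to intercept shifts and equivariant to translation", {
  set.seed(7)
  s <- random_quadratic()
  cf <- s$coefficients
  shifted <- quadratic_surface(cf["a"], cf["b"], cf["c"], cf["d"], cf["e"],
                               cf["intercept"] + 123.45)
  xs <- runif(50, -2, 2); ys <- runif(50, -2, 2)
  f1 <- fundamental_forms(s, xs, ys); f2 <- fundamental_forms(shifted, xs, ys)
  expect_identical(gauss_curvature(f1), gauss_curvature(f2))
  expect_identical(mean_curvature(f1), mean_curvature(f2))
  expect_identical(principal_curvatures(f1), principal_curvatures(f2))

  # replacing f(x, y) by f(x - u, y - v) translates the curvature fields
  u <- 0.7; v <- -1.2
  translated <- surface_patch(
    height = function(x, y) s$height(x - u, y - v),
    dx = function(x, y) s$dx(x - u, y - v),
    dy = function(x, y) s$dy(x - u, y - v),
    dxx = function(x, y) s$dxx(x - u, y - v),
    dyy = function(x, y) s$dyy(x - u, y - v),
    dxy = function(x, y) s$dxy(x - u, y - v))
  ft <- fundamental_forms(translated, xs + u, ys + v)
  expect_equal(gauss_curvature(ft), gauss_curvature(f1))
  expect_equal(mean_curvature(ft), mean_curvature(f1))
})
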