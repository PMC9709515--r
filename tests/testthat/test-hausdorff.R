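test_that("mean standardization gives mean exactly 1 and preserves shape", {
  expect_equal(mean_standardize(c(1, 2, 3)), c(0.5, 1, 1.5))
  set.seed(5)
  v <- rexp(100) + 1
  expect_equal(mean(mean_standardize(v)), 1)
  expect_equal(mean_standardize(v) * mean(v), v)
  expect_error(mean_standardize(rep(0, 5)), "degenerate")
  expect_error(mean_standardize(c(-1, 1)), "degenerate")
})

test_that("worked 1-D example: {1,2} vs {1,2,3,4}", {
  A <- c(1, 2); B <- c(1, 2, 3, 4)
  expect_identical(directed_hausdorff(A, B), 0)   # A is a subset of B
  expect_identical(directed_hausdorff(B, A), 2)
  d <- hausdorff_distance(A, B)
  expect_identical(as.numeric(d), 2)
  expect_identical(attr(d, "directed"), c(mn = 0, nm = 2))
})

test_that("directed distance handles basic cases and errors", {
  expect_equal(directed_hausdorff(matrix(c(0, 0, 0), 1),
                                  matrix(c(3, 4, 0), 1)), 5)
  expect_error(directed_hausdorff(matrix(0, 0, 2), matrix(0, 1, 2)), "empty")
  expect_error(directed_hausdorff(matrix(0, 1, 2), matrix(0, 1, 3)),
               "dimension mismatch")
  expect_error(directed_hausdorff(c(NA, 1), c(1, 2)), "non-finite")
})

test_that("compiled kernel equals the brute-force double loop exactly", {
  set.seed(6)
  for (i in 1:5) {
    nA <- sample(50:500, 1); nB <- sample(50:500, 1)
    A <- matrix(rnorm(nA * 3), ncol = 3)
    B <- matrix(rnorm(nB * 3), ncol = 3)
    expect_identical(directed_hausdorff(A, B), brute_directed_hausdorff(A, B))
    expect_identical(as.numeric(hausdorff_distance(A, B)),
                     brute_hausdorff(A, B))
  }
  # cross-check against an independent library implementation
  A <- matrix(rnorm(200 * 3), ncol = 3); B <- matrix(rnorm(150 * 3), ncol = 3)
  expect_equal(as.numeric(hausdorff_distance(A, B)),
               pracma::hausdorff_dist(A, B), tolerance = 1e-12)
})

test_that("Hausdorff distance satisfies the metric axioms on point sets", {
  set.seed(8)
  for (i in 1:100) {
    A <- matrix(rnorm(sample(2:10, 1) * 2), ncol = 2)
    B <- matrix(rnorm(sample(2:10, 1) * 2), ncol = 2)
    C <- matrix(rnorm(sample(2:10, 1) * 2), ncol = 2)
    dAB <- as.numeric(hausdorff_distance(A, B))
    dBA <- as.numeric(hausdorff_distance(B, A))
    expect_identical(dAB, dBA)                                   # symmetry
    dAC <- as.numeric(hausdorff_distance(A, C))
    dBC <- as.numeric(hausdorff_distance(B, C))
    expect_lte(dAC, dAB + dBC + 1e-12)                           # triangle
  }
  A <- matrix(rnorm(20), ncol = 2)
  expect_identical(as.numeric(hausdorff_distance(A, A)), 0)      # identity
})

test_that("landscape distancing needs a shared template and detects identity", {
  flat <- canonical_flat(n = 21)
  expect_identical(as.numeric(hausdorff_distance(flat, flat)), 0)
  saddle_fine <- canonical_saddle(n = 31)
  expect_error(hausdorff_distance(flat, saddle_fine), "template")
  saddle <- canonical_saddle(n = 21)
  d1 <- hausdorff_distance(flat, saddle)
  d2 <- hausdorff_distance(saddle, flat)
  expect_identical(as.numeric(d1), as.numeric(d2))
})

test_that("a single perturbed node moves the distance by exactly its z offset", {
  # standardized point clouds differing at one node by delta in z: d_H = delta
  xy <- as.matrix(expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1)))
  pts_m <- cbind(xy, z = 1)
  pts_n <- pts_m
  delta0 <- 0.05                         # below the 0.1 node spacing
  pts_n[61, "z"] <- 1 + delta0
  expect_equal(as.numeric(hausdorff_distance(pts_m, pts_n)), delta0)
  expect_identical(as.numeric(hausdorff_distance(pts_m, pts_n)),
                   brute_hausdorff(pts_m, pts_n))

  m <- canonical_flat(n = 11)
  n <- canonical_flat(n = 11)
  delta <- 0.3
  # perturb one interior node; mean-standardization rescales both sides
  n$z[6, 6] <- n$z[6, 6] + delta * 121
  # after standardization: m is all 1, n is 1 everywhere except 1 + delta*121/mean
  zm <- mean_standardize(as.vector(m$z))
  zn <- mean_standardize(as.vector(n$z))
  expected <- brute_hausdorff(
    cbind(minmax_standardize(as.data.frame(m)$x),
          minmax_standardize(as.data.frame(m)$y), zm),
    cbind(minmax_standardize(as.data.frame(n)$x),
          minmax_standardize(as.data.frame(n)$y), zn))
  expect_equal(as.numeric(hausdorff_distance(m, n)), expected)
  expect_gt(expected, 0)
})

test_that("mean-standardization makes d_H scale-invariant in raw z", {
  set.seed(9)
  s <- random_quadratic()
  cf <- s$coefficients
  g1 <- predict_grid(s, c(1, 1), n = 15)
  scaled <- quadratic_surface(3 * cf["a"], 3 * cf["b"], 3 * cf["c"],
                              3 * cf["d"], 3 * cf["e"], 3 * cf["intercept"])
  g2 <- predict_grid(scaled, c(1, 1), n = 15)
  ref <- canonical_saddle(n = 15)
  expect_equal(as.numeric(hausdorff_distance(g1, ref)),
               as.numeric(hausdorff_distance(g2, ref)), tolerance = 1e-12)
})

test_that("bootstrap is seeded, degenerate on identical landscapes, and concentrates", {
  flat <- canonical_flat(n = 15)
  saddle <- canonical_saddle(n = 15)
  h1 <- hausdorff_bootstrap(flat, saddle, n_boot = 50, seed = 4)
  h2 <- hausdorff_bootstrap(flat, saddle, n_boot = 50, seed = 4)
  expect_identical(h1$t, h2$t)
  expect_lte(h1$lwr95, h1$upr95)
  expect_equal(h1$d_H, as.numeric(hausdorff_distance(flat, saddle)))

  same <- hausdorff_bootstrap(flat, canonical_flat(n = 15),
                              n_boot = 20, seed = 1)
  expect_identical(c(same$d_H, same$mean, same$sd), c(0, 0, 0))

  # resampling noise shrinks as the grid grows, on average over seeds
  sds <- sapply(c(8, 24), function(n) {
    f <- canonical_flat(n = n); s <- canonical_saddle(n = n)
    mean(sapply(1:20, function(sd_seed)
      hausdorff_bootstrap(f, s, n_boot = 30, seed = sd_seed)$sd))
  })
  expect_lt(sds[2], sds[1])
})
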