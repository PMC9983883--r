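test_that("cubic basis weights match their closed form", {
  expect_equal(basis_weights(0), c(1, 4, 1, 0) / 6)
  u <- 1 - 1e-9
  expect_equal(basis_weights(u), c(0, 1, 4, 1) / 6, tolerance = 1e-7)
  for (u in runif(10)) {
    b <- basis_weights(u)
    expect_true(all(b >= 0))
    expect_equal(sum(b), 1)
  }
  expect_error(basis_weights(1))
})

test_that("zero and constant meshes reproduce identity and translation", {
  set.seed(2)
  for (counts in list(c(4, 4), c(6, 9), c(5, 4, 4))) {
    n <- length(counts)
    ext <- runif(n, 20, 60)
    f <- bspline_field(counts, ext)
    pts <- matrix(runif(12 * n, 0, rep(ext, each = 12)), 12, n)
    expect_equal(transform_points(f, pts), pts, tolerance = 1e-14)
    v <- runif(n, -3, 3)
    f$phi <- matrix(rep(v, each = nrow(f$phi)), ncol = n)
    expect_equal(transform_points(f, pts), sweep(pts, 2, v, "+"),
                 tolerance = 1e-12)
  }
  # identity outside the support
  f <- bspline_field(c(6, 6), c(31, 31))
  f$phi[] <- 5
  out <- rbind(c(-1, 10), c(10, 33))
  expect_equal(transform_points(f, out), out)
})

test_that("a single control point displaces by its tensor-product weight", {
  f <- bspline_field(c(6, 6), c(30, 30))  # delta = 10, origin = -10
  f$phi[3 + (3 - 1) * 6, 1] <- 2  # control (3, 3) 1-based
  # x chosen so t = (x + 10)/10 -> z and u known: x = (12, 17)
  t <- (c(12, 17) + 10) / 10
  z <- floor(t); u <- t - z
  # supports are controls (z - 1) + o for o = 0..3 (0-based mesh coords);
  # control (3, 3) is 0-based (2, 2), so o = 2 - (z - 1)
  w <- basis_weights(u[1])[2 - (z[1] - 1) + 1] *
       basis_weights(u[2])[2 - (z[2] - 1) + 1]
  d <- transform_points(f, rbind(c(12, 17))) - rbind(c(12, 17))
  expect_equal(d[1, 1], 2 * w)
  expect_equal(d[1, 2], 0)
})

test_that("parameter Jacobian holds the basis weights", {
  f <- bspline_field(c(6, 6), c(30, 30))
  # x at a knot: u = 0 in both dims -> 1D weight pattern (1/6, 4/6, 1/6, 0)
  jac <- param_jacobian(f, rbind(c(10, 10)))
  expect_true(jac$inside[1])
  w <- sort(unique(round(jac$w[1, ], 12)), decreasing = TRUE)
  expect_equal(max(jac$w[1, ]), (4 / 6)^2)
  expect_equal(sum(jac$w[1, ]), 1)
  # outside the support: empty
  jac <- param_jacobian(f, rbind(c(-5, 10)))
  expect_false(jac$inside[1])
  expect_true(all(jac$idx[1, ] == 0))
  # linearity: T is affine in the parameters (superposition)
  set.seed(4)
  pts <- matrix(runif(10, 0, 30), 5, 2)
  p1 <- matrix(rnorm(72), 36, 2)
  p2 <- matrix(rnorm(72), 36, 2)
  d <- function(phi) {
    g <- bspline_field(c(6, 6), c(30, 30), phi = phi)
    transform_points(g, pts) - pts
  }
  expect_equal(d(p1 + 2 * p2), d(p1) + 2 * d(p2), tolerance = 1e-12)
})

test_that("locality: one control point only acts inside its support box", {
  f0 <- bspline_field(c(8, 8), c(35, 35))
  f1 <- f0
  i <- 4; j <- 5  # 1-based mesh indices
  f1$phi[i + (j - 1) * 8, ] <- c(3, -2)
  g <- as.matrix(expand.grid(seq(0, 35, by = 0.7), seq(0, 35, by = 0.7)))
  d <- transform_points(f1, g) - transform_points(f0, g)
  moved <- rowSums(abs(d)) > 1e-12
  # support box of control (i-1, j-1) 0-based at position (c0 + k*delta):
  ctr <- (c(i, j) - 1) * f0$delta + f0$origin
  inside_box <- abs(g[, 1] - ctr[1]) < 2 * f0$delta[1] &
                abs(g[, 2] - ctr[2]) < 2 * f0$delta[2]
  expect_true(all(inside_box[moved]))
})

test_that("composition equals sequential application and cancels inverses", {
  set.seed(5)
  a <- bspline_field(c(6, 6), c(31, 31), phi = matrix(rnorm(72, 0, 0.5), 36, 2))
  b <- bspline_field(c(7, 7), c(31, 31), phi = matrix(rnorm(98, 0, 0.5), 49, 2))
  pts <- matrix(runif(16, 4, 27), 8, 2)
  expect_equal(compose_points(a, b, pts),
               transform_points(a, transform_points(b, pts)))
  # constant +v then constant -v: identity at interior points
  fv <- bspline_field(c(6, 6), c(31, 31))
  fv$phi[] <- rep(c(2, 1), each = 36)
  fm <- fv; fm$phi <- -fv$phi
  interior <- rbind(c(10, 12), c(20, 8))
  expect_equal(compose_points(fm, fv, interior), interior,
               tolerance = 1e-12)
})

test_that("mesh refinement reproduces the input field", {
  set.seed(6)
  ext <- c(40, 40)
  g <- as.matrix(expand.grid(seq(0, 40, by = 0.5), seq(0, 40, by = 0.5)))
  diam <- sqrt(sum(ext^2))
  # zero field stays zero
  z <- refine(bspline_field(c(5, 5), ext), c(9, 9))
  expect_equal(max(abs(z$phi)), 0)
  # nested doubling (c' = 2c - 3) is exact for random smooth fields
  for (rep in 1:3) {
    f <- bspline_field(c(6, 6), ext, phi = matrix(rnorm(72, 0, 3), 36, 2))
    fr <- refine(f, c(9, 9))
    err <- max(abs(transform_points(fr, g) - transform_points(f, g)))
    expect_lt(err, 1e-6 * diam)
  }
  # constant translation survives refinement in the interior
  fc <- bspline_field(c(5, 5), ext)
  fc$phi[] <- rep(c(1.5, -2), each = 25)
  fr <- refine(fc, c(12, 12))
  interior <- matrix(runif(20, 5, 35), 10, 2)
  expect_equal(transform_points(fr, interior),
               sweep(interior, 2, c(1.5, -2), "+"), tolerance = 1e-9)
  # contract: counts must not shrink, sampling must stay determined
  expect_error(refine(fc, c(4, 4)))
  expect_error(refine(fc, c(12, 12), samples_per_span = 2), "samples")
})

test_that("physical coordinates make fields resolution-independent", {
  # the same field evaluated on a coarse grid (doubled spacing) agrees with
  # the fine evaluation at matching physical positions
  set.seed(9)
  f <- bspline_field(c(6, 6), c(31, 31), phi = matrix(rnorm(72), 36, 2))
  pts <- matrix(runif(10, 2, 29), 5, 2)
  expect_equal(transform_points(f, pts), transform_points(f, pts))
  img_fine <- fuzzy_image(matrix(runif(32 * 32), 32, 32), spacing = 1)
  img_coarse <- fuzzy_image(matrix(runif(16 * 16), 16, 16), spacing = 2)
  expect_equal(image_extent(img_fine)$extent, c(31, 31))
  expect_equal(image_extent(img_coarse)$extent, c(30, 30))
})
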