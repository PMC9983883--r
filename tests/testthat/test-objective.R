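# small binary scene shared by several tests
binary_scene <- function(seed = 21, n = 16) {
  set.seed(seed)
  img <- matrix(0, n, n)
  img[5:9, 4:12] <- 1
  img[12:13, 3:7] <- 1
  fuzzy_image(img)
}

test_that("matching an image to itself under identity has zero distance", {
  img <- binary_scene()
  trees <- alpha_trees(img)
  ext <- image_extent(img)$extent
  f <- bspline_field(c(4, 4), ext)
  cfg <- mc_config(d_max = 8, alphas = c(0.25, 0.5, 0.75))
  res <- directed_amd(all_points(img), f, trees, img, cfg)
  expect_equal(res$value, 0)
  expect_equal(sum(res$kept), prod(img$N))
})

test_that("a single fuzzy point at distance r scores r", {
  img <- fuzzy_image({
    m <- matrix(0, 16, 16)
    m[4, 7] <- 1  # object spel at 0-based (3, 6)
    m
  })
  trees <- alpha_trees(img)
  f <- bspline_field(c(4, 4), image_extent(img)$extent)
  p <- list(pos = rbind(c(8, 6)), height = 1, weight = 1)  # r = 5
  cfg <- mc_config(d_max = 12, alphas = c(0.2, 0.5, 0.9))
  res <- directed_amd(p, f, trees, img, cfg)
  expect_equal(res$value, 5, tolerance = 1e-12)
})

test_that("the directed distance is invariant to uniform weight scaling", {
  set.seed(33)
  img <- rand_image(12)
  trees <- alpha_trees(img)
  f <- bspline_field(c(5, 5), image_extent(img)$extent,
                     phi = matrix(rnorm(50, 0, 0.4), 25, 2))
  P <- all_points(img)
  cfg <- mc_config(d_max = 6, alphas = sort(runif(5)))
  r1 <- directed_amd(P, f, trees, img, cfg)
  P$weight <- P$weight * 7
  r2 <- directed_amd(P, f, trees, img, cfg)
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
  # raw gradient scales with the weights (the ratio property used by the
  # optimizer scaling)
  expect_equal(r2$ctrl_grad_raw, 7 * r1$ctrl_grad_raw, tolerance = 1e-12)
})

test_that("pointwise inverse inconsistency matches its definition", {
  ext <- c(31, 31)
  id <- bspline_field(c(6, 6), ext)
  shift <- bspline_field(c(6, 6), ext)
  shift$phi[] <- rep(c(2, -1), each = 36)
  x <- rbind(c(10, 12), c(15, 20))
  expect_equal(point_iic(id, id, x), c(0, 0))
  # forward shift then identity: residual is the shift itself
  expect_equal(point_iic(shift, id, x),
               rep(0.5 * sum(c(2, -1)^2), 2), tolerance = 1e-12)
  # mutually inverse constant shifts cancel
  inv <- shift; inv$phi <- -shift$phi
  expect_equal(point_iic(shift, inv, x), c(0, 0), tolerance = 1e-20)
  set.seed(14)
  f1 <- bspline_field(c(6, 6), ext, phi = matrix(rnorm(72), 36, 2))
  f2 <- bspline_field(c(6, 6), ext, phi = matrix(rnorm(72), 36, 2))
  expect_true(all(point_iic(f1, f2, matrix(runif(40, 0, 31), 20, 2)) >= 0))
})

test_that("average inverse inconsistency and its gradients", {
  img <- binary_scene()
  ext <- image_extent(img)$extent
  id <- bspline_field(c(6, 6), ext)
  shift <- bspline_field(c(6, 6), ext)
  shift$phi[] <- rep(c(1, 0.5), each = 36)
  inv <- shift; inv$phi <- -shift$phi
  P <- all_points(img)
  expect_equal(aw_iic(shift, inv, P, img)$value, 0, tolerance = 1e-18)
  # constant residual r at every kept point: value = ||r||^2 / 2
  res <- aw_iic(shift, id, P, img)
  expect_equal(res$value, 0.5 * sum(c(1, 0.5)^2), tolerance = 1e-12)
  # gradients against central finite differences
  set.seed(41)
  f1 <- bspline_field(c(6, 6), ext, phi = matrix(rnorm(72, 0, 0.5), 36, 2))
  f2 <- bspline_field(c(6, 6), ext, phi = matrix(rnorm(72, 0, 0.5), 36, 2))
  Ps <- all_points(img)
  keep <- seq(1, 256, by = 3)
  Ps <- list(pos = Ps$pos[keep, ], height = Ps$height[keep],
             weight = Ps$weight[keep])
  base <- aw_iic(f1, f2, Ps, img)
  h <- 1e-5
  for (k in 1:6) {
    i <- sample(36, 1); cmp <- sample(2, 1)
    for (which_field in 1:2) {
      fp <- list(f1, f2); fm <- list(f1, f2)
      fp[[which_field]]$phi[i, cmp] <- fp[[which_field]]$phi[i, cmp] + h
      fm[[which_field]]$phi[i, cmp] <- fm[[which_field]]$phi[i, cmp] - h
      vp <- aw_iic(fp[[1]], fp[[2]], Ps, img)
      vm <- aw_iic(fm[[1]], fm[[2]], Ps, img)
      fd <- (vp$value - vm$value) / (2 * h) * base$w_sum
      an <- if (which_field == 1) base$grad_fwd_raw[i, cmp]
            else base$grad_bwd_raw[i, cmp]
      if (max(abs(fd), abs(an)) > 1e-10)
        expect_lt(abs(an - fd) / max(abs(fd), abs(an)), 1e-3)
    }
  }
})

test_that("the total objective assembles, is symmetric, and recomposes", {
  set.seed(51)
  A <- binary_scene(51)
  B <- binary_scene(52)
  trA <- alpha_trees(A); trB <- alpha_trees(B)
  ext <- image_extent(A)$extent
  TAB <- bspline_field(c(5, 5), ext, phi = matrix(rnorm(50, 0, 0.3), 25, 2))
  TBA <- bspline_field(c(5, 5), ext, phi = matrix(rnorm(50, 0, 0.3), 25, 2))
  P_A <- all_points(A); P_B <- all_points(B)
  cfg <- mc_config(d_max = 7, alphas = c(0.3, 0.6, 0.9))
  lam <- 0.4
  pair <- objective_pair(TAB, TBA, lambda = lam)
  rep1 <- total_objective(pair, A, B, trA, trB, P_A, P_B, cfg)

  # recomposition from the standalone operations
  d1 <- directed_amd(P_A, TAB, trB, B, cfg)
  d2 <- directed_amd(P_B, TBA, trA, A, cfg)
  i1 <- aw_iic(TAB, TBA, P_A, B)
  i2 <- aw_iic(TBA, TAB, P_B, A)
  expect_equal(rep1$J,
               0.5 * (d1$value + d2$value) + lam / 2 * (i1$value + i2$value),
               tolerance = 1e-14)
  expect_equal(unname(rep1$components),
               c(d1$value, d2$value, i1$value, i2$value), tolerance = 1e-14)
  expect_equal(rep1$J, 0.5 * (rep1$components[["d_AB"]] +
                              rep1$components[["d_BA"]]) +
                 lam / 2 * (rep1$components[["iic_AB"]] +
                            rep1$components[["iic_BA"]]))

  # exact symmetry under swapping roles
  pair_sw <- objective_pair(TBA, TAB, lambda = lam)
  rep2 <- total_objective(pair_sw, B, A, trB, trA, P_B, P_A, cfg)
  expect_identical(rep1$J, rep2$J)
  expect_identical(rep1$grad_AB, rep2$grad_BA)

  # lambda = 0 leaves the pure symmetric distance mean
  rep0 <- total_objective(objective_pair(TAB, TBA, 0), A, B, trA, trB,
                          P_A, P_B, cfg)
  expect_equal(rep0$J, 0.5 * (d1$value + d2$value), tolerance = 1e-14)

  # increasing lambda never decreases J for a fixed configuration
  Js <- vapply(c(0, 0.1, 0.5, 2),
               function(l) total_objective(objective_pair(TAB, TBA, l),
                                           A, B, trA, trB, P_A, P_B,
                                           cfg)$J, numeric(1))
  expect_true(all(diff(Js) >= 0))
})

test_that("small residuals are dominated by the distance term", {
  # scaling a perturbation down: the quadratic inconsistency term vanishes
  # faster than the (first-order) distance term
  set.seed(61)
  A <- binary_scene(61)
  trA <- alpha_trees(A)
  ext <- image_extent(A)$extent
  cfg <- mc_config(d_max = 7, alphas = c(0.3, 0.6, 0.9))
  P <- all_points(A)
  base <- bspline_field(c(5, 5), ext)
  dphi <- matrix(rnorm(50, 0, 1), 25, 2)
  vals <- t(vapply(c(0.2, 0.02), function(s) {
    f <- bspline_field(c(5, 5), ext, phi = s * dphi)
    pr <- objective_pair(f, base, lambda = 1)
    r <- total_objective(pr, A, A, trA, trA, P, P, cfg)
    c(dist = unname(r$components["d_AB"]),
      iic = unname(r$components["iic_AB"]))
  }, numeric(2)))
  ratio1 <- vals[1, "iic"] / max(vals[1, "dist"], 1e-12)
  ratio2 <- vals[2, "iic"] / max(vals[2, "dist"], 1e-12)
  expect_lt(ratio2, ratio1)  # the IIC share shrinks with the perturbation
})

test_that("no overlap between the images raises an informative error", {
  img <- binary_scene()
  trees <- alpha_trees(img)
  f <- bspline_field(c(4, 4), image_extent(img)$extent)
  f$phi[] <- 100  # push every point far outside the target grid
  cfg <- mc_config(d_max = 5, alphas = 0.5)
  expect_error(directed_amd(all_points(img), f, trees, img, cfg),
               "no overlap")
})

test_that("analytic objective gradient matches central differences", {
  # scaled-down version of the acceptance check (random gray-scale pair)
  set.seed(71)
  A <- fuzzy_image(matrix(runif(16 * 16), 16, 16))
  B <- fuzzy_image(matrix(runif(16 * 16), 16, 16))
  trA <- alpha_trees(A); trB <- alpha_trees(B)
  ext <- image_extent(A)$extent
  pair <- objective_pair(
    bspline_field(c(5, 5), ext, phi = matrix(rnorm(50, 0, 0.4), 25, 2)),
    bspline_field(c(5, 5), ext, phi = matrix(rnorm(50, 0, 0.4), 25, 2)),
    lambda = 0.01)
  cfg <- mc_config(d_max = 6, stencil = "exact",
                   alphas = exhaustive_alphas(A, B))
  P_A <- draw_points(A, 25, sampler_config(m = 0, fraction = 0.1))
  P_B <- draw_points(B, 25, sampler_config(m = 0, fraction = 0.1))
  rep0 <- total_objective(pair, A, B, trA, trB, P_A, P_B, cfg)
  h <- 1e-3 * pair$T_AB$delta[1]
  worst <- 0
  for (i in sample(25, 5)) for (cmp in 1:2) {
    pp <- pair; pm <- pair
    pp$T_AB$phi[i, cmp] <- pp$T_AB$phi[i, cmp] + h
    pm$T_AB$phi[i, cmp] <- pm$T_AB$phi[i, cmp] - h
    fd <- (total_objective(pp, A, B, trA, trB, P_A, P_B, cfg)$J -
           total_objective(pm, A, B, trA, trB, P_A, P_B, cfg)$J) / (2 * h)
    an <- rep0$grad_AB[i, cmp]
    if (max(abs(fd), abs(an)) > 1e-8)
      worst <- max(worst, abs(an - fd) / max(abs(fd), abs(an)))
  }
  expect_lt(worst, 1e-3)
})
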