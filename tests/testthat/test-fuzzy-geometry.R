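test_that("tree construction stores per-rectangle maxima", {
  # constant image: every node equals the constant
  img <- fuzzy_image(matrix(0.4, 8, 8))
  tr <- alpha_tree(img)
  expect_true(all(tr$values[tr$values >= 0] == 0.4))

  set.seed(101)
  img <- rand_image(8)
  tr <- alpha_tree(img)
  expect_equal(tr$values[2], max(img$mu))
  # every node equals the brute-force max over its rectangle, for both the
  # object and the complement tree
  trc <- alpha_tree(img, complement = TRUE)
  for (nd in enumerate_tree_rects(img$N, img$spacing)) {
    sub <- img$mu[nd$y[1] + seq_len(nd$R[1]), nd$y[2] + seq_len(nd$R[2])]
    expect_identical(tr$values[nd$i + 1], max(sub))
    expect_identical(trc$values[nd$i + 1], max(1 - sub))
  }
})

test_that("rectangle splitting follows the longest-axis rule", {
  s <- split_rect(c(0, 0), c(4, 2), c(1, 1))
  expect_equal(s$axis, 1)
  expect_equal(s$left$R, c(2L, 2L))
  expect_equal(s$right$R, c(2L, 2L))
  expect_equal(s$right$y, c(2L, 0L))
  # spacing-weighted: s * (R - 1) = (2, 4) -> axis 2
  s <- split_rect(c(0, 0), c(3, 3), c(1, 2))
  expect_equal(s$axis, 2)
  expect_equal(s$left$R, c(3L, 2L))
  # tie broken by the lowest dimension
  s <- split_rect(c(0, 0), c(2, 2), c(1, 1))
  expect_equal(s$axis, 1)
  expect_error(split_rect(c(0, 0), c(1, 1), c(1, 1)), "leaf")
})

test_that("rectangle lower bounds are valid and tight", {
  expect_equal(rect_lower_bound(c(1.2, 0.7), c(0, 0), c(3, 3), c(1, 1)), 0)
  expect_equal(rect_lower_bound(c(5, 5), c(0, 0), c(3, 3), c(1, 1)),
               sqrt(18))
  expect_equal(rect_lower_bound(c(1, 2), c(2, 2), c(4, 1), c(1, 1)), 1)
  # never exceeds the distance to any spel center inside the rectangle
  set.seed(7)
  for (k in 1:25) {
    p <- runif(2, -4, 12)
    y <- sample(0:5, 2, replace = TRUE)
    R <- sample(1:3, 2, replace = TRUE)
    b <- rect_lower_bound(p, y, R, c(1, 1))
    cells <- as.matrix(expand.grid(y[1] + 0:(R[1] - 1),
                                   y[2] + 0:(R[2] - 1)))
    expect_lte(b, min(sqrt(rowSums(sweep(cells, 2, p, "-")^2))) + 1e-12)
  }
})

test_that("relaxed bound matches its closed form", {
  set.seed(8)
  for (k in 1:10) {
    p <- runif(2, -10, 20)
    y <- c(0, 0); R <- c(4, 4)
    expect_identical(relaxed_lower_bound(p, y, R, c(1, 1), d_t = 5,
                                         beta = 1),
                     rect_lower_bound(p, y, R, c(1, 1)))
  }
  # bound above the threshold is inflated: 20 + 1.2 * (30 - 20) = 32
  expect_equal(cpp_relaxed_bound(30, 20, 1.2), 32)
  expect_equal(cpp_relaxed_bound(10, 20, 1.2), 10)
})

test_that("tree search with beta = 1 equals exhaustive nearest-spel scan", {
  set.seed(31)
  for (case in 1:20) {
    img <- rand_image(8)
    tr <- alpha_tree(img)
    base <- sample(0:6, 2, replace = TRUE)
    corners <- as.matrix(expand.grid(base[1] + 0:1, base[2] + 0:1))
    a <- runif(1)
    D <- alpha_cut_search(corners, a, tr, d_init = 100)
    ref <- vapply(seq_len(4), function(j)
      brute_cut_distance(corners[j, ], img, a, d_max = 100), numeric(1))
    expect_identical(as.numeric(D), ref)
  }
  # empty alpha-cut: all corners keep d_init
  img <- fuzzy_image(matrix(0.3, 8, 8))
  tr <- alpha_tree(img)
  corners <- as.matrix(expand.grid(2:3, 2:3))
  expect_identical(as.numeric(alpha_cut_search(corners, 0.9, tr, 50)),
                   rep(50, 4))
  # a corner on a spel at/above the level has distance 0
  img <- rand_image(8)
  img$mu[4, 5] <- 0.95
  tr <- alpha_tree(img)
  D <- alpha_cut_search(rbind(c(3, 4), c(3, 5), c(4, 4), c(4, 5)), 0.95,
                        tr, 100)
  expect_equal(D[1, 1], 0)
})

test_that("joint multi-level search equals the single-level reference path", {
  set.seed(55)
  for (case in 1:10) {
    img <- rand_image(8)
    tr <- alpha_tree(img)
    corners <- as.matrix(expand.grid(2:3, 4:5))
    alphas <- sort(runif(6))
    for (beta in c(1, 1.2, 2)) {
      Dj <- alpha_cut_search(corners, alphas, tr, 100, d_t = 2, beta = beta,
                             joint = TRUE)
      Ds <- alpha_cut_search(corners, alphas, tr, 100, d_t = 2, beta = beta,
                             joint = FALSE)
      expect_identical(Dj, Ds)
    }
  }
})

test_that("relaxed search honors its approximation contract", {
  # exact whenever the true distance is at or below d_t; never above
  # d_t + beta * (true - d_t)
  set.seed(77)
  d_t <- 3; beta <- 1.3
  for (case in 1:30) {
    img <- rand_image(8)
    tr <- alpha_tree(img)
    base <- sample(0:6, 2, replace = TRUE)
    corners <- as.matrix(expand.grid(base[1] + 0:1, base[2] + 0:1))
    a <- runif(1, 0.5, 1)
    D <- as.numeric(alpha_cut_search(corners, a, tr, 100, d_t = d_t,
                                     beta = beta))
    truth <- vapply(seq_len(4), function(j)
      brute_cut_distance(corners[j, ], img, a, d_max = 100), numeric(1))
    expect_true(all(D >= truth - 1e-12))
    expect_true(all(D <= pmax(truth, d_t + beta * (truth - d_t)) + 1e-12))
    exact <- truth <= d_t
    expect_identical(D[exact], truth[exact])
  }
})

test_that("Monte-Carlo estimate matches the exhaustive-scan oracle", {
  # shared alpha levels: the tree path and the O(N)-scan oracle agree
  set.seed(13)
  for (case in 1:6) {
    img <- rand_image(6)
    trees <- alpha_trees(img)
    alphas <- exhaustive_alphas(img)
    for (rep in 1:3) {
      p <- runif(2, 0, 5)
      h <- runif(1)
      mc <- mc_point_distance(p, h, trees, alphas, d_max = 4)
      ex <- exact_alpha_distance(p, h, img, alphas, d_max = 4)
      expect_equal(mc$value, ex$value, tolerance = 1e-12)
      expect_equal(as.numeric(mc$corner), as.numeric(ex$corner),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate fuzzy points have zero distance", {
  # point on a full-membership spel of a binary image, h = 1: every sampled
  # level takes the inward branch and lands on the spel
  img <- fuzzy_image(matrix(as.numeric(matrix(runif(64), 8, 8) > 0.6), 8, 8))
  img$mu[4, 4] <- 1
  trees <- alpha_trees(img)
  mc <- mc_point_distance(c(3, 3), 1, trees, runif(20), d_max = 10)
  expect_equal(mc$value, 0)
  # symmetric case: h = 0 on an empty spel, complement branch distance 0
  img$mu[6, 2] <- 0
  trees <- alpha_trees(img)
  mc <- mc_point_distance(c(5, 1), 0, trees, runif(20), d_max = 10)
  expect_equal(mc$value, 0)
})

test_that("out-of-domain points are signalled", {
  img <- rand_image(6)
  trees <- alpha_trees(img)
  expect_error(mc_point_distance(c(-0.6, 2), 0.5, trees, 0.5, d_max = 5),
               "out")
  expect_error(mc_point_distance(c(2, 5.4), 0.5, trees, 0.5, d_max = 5),
               "out")
  # the grid-hull boundary itself is in-domain
  expect_silent(mc_point_distance(c(5, 5), 0.5, trees, 0.5, d_max = 5))
})

test_that("d' is monotone in alpha below the height and truncated at d_max", {
  set.seed(17)
  img <- rand_image(8)
  trees <- alpha_trees(img)
  d_max <- 6
  for (rep in 1:10) {
    p <- runif(2, 0, 7)
    h <- runif(1, 0.5, 1)
    alphas <- sort(runif(8, 0, h))
    D <- vapply(alphas, function(a)
      mc_point_distance(p, h, trees, a, d_max = d_max)$value, numeric(1))
    expect_true(all(diff(D) >= -1e-12))
    expect_true(all(D >= 0 & D <= d_max))
  }
})

test_that("level-set quadrature matches hand-computed cases", {
  # single-spel object: each level alpha <= mu contributes the plain
  # distance, levels above contribute through the complement branch
  img <- fuzzy_image(matrix(0, 9, 9))
  img$mu[3, 5] <- 0.8
  p <- c(7, 4)  # distance 5 from the object spel (at (2, 4))
  # h = 0.8: inward integral over (0, 0.8] of d = 5; complement cut is the
  # whole domain minus the spel for every level, so its distance is 0
  q <- exact_alpha_quadrature(p, 0.8, img, d_max = 20)
  expect_equal(q, 0.8 * 5, tolerance = 1e-12)
  # empty cut saturates at d_max: membership zero everywhere, h = 1
  img0 <- fuzzy_image(matrix(0, 6, 6))
  expect_equal(exact_alpha_quadrature(c(2, 2), 1, img0, d_max = 7), 7)
})

test_that("uniform alpha sampling is unbiased for the level quadrature", {
  # scaled-down version of the full acceptance check
  set.seed(23)
  img <- rand_image(6)
  trees <- alpha_trees(img)
  p <- c(2.4, 3.1); h <- 0.55; d_max <- 4
  q <- exact_alpha_quadrature(p, h, img, d_max)
  n <- 20000
  alphas <- runif(n)
  est <- mc_point_distance(p, h, trees, alphas, d_max)
  # per-sample interpolated d' values, for the Monte-Carlo standard error
  cc_base <- floor(p)
  corners <- as.matrix(expand.grid(cc_base[1] + 0:1, cc_base[2] + 0:1))
  u <- p - cc_base
  w <- c((1 - u[1]) * (1 - u[2]), u[1] * (1 - u[2]),
         (1 - u[1]) * u[2], u[1] * u[2])
  obj <- sort(alphas[alphas <= h])
  com <- sort(1 - alphas[alphas > h])
  D <- rbind(
    if (length(obj)) alpha_cut_search(corners, obj, trees$object, d_max),
    if (length(com)) alpha_cut_search(corners, com, trees$complement, d_max))
  draws <- as.numeric(D %*% w)
  expect_equal(mean(draws), est$value, tolerance = 1e-12)
  se <- stats::sd(draws) / sqrt(n)
  expect_lt(abs(est$value - q), 3 * se)
})

test_that("the estimator generalizes to 3D volumes", {
  set.seed(19)
  vol <- fuzzy_image(array(runif(5 * 5 * 5), c(5, 5, 5)),
                     spacing = c(1, 1, 2))
  trees <- alpha_trees(vol)
  expect_equal(trees$object$values[2], max(vol$mu))
  alphas <- sort(runif(7))
  for (rep in 1:5) {
    p <- c(runif(2, 0.2, 3.8), runif(1, 0.4, 7.6))
    h <- runif(1)
    mc <- mc_point_distance(p, h, trees, alphas, d_max = 5)
    ex <- exact_alpha_distance(p, h, vol, alphas, d_max = 5)
    expect_equal(mc$value, ex$value, tolerance = 1e-12)
    expect_length(mc$corner, 8)
    expect_length(mc$grad_mid, 3)
  }
})
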