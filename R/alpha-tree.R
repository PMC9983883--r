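#' Augmented max KD-tree over an image grid
#'
#' Builds the implicit array-stored KD-tree used by the Monte-Carlo alpha-cut
#' distance estimator.  Node `i` stores the maximum membership of its
#' sub-rectangle (children at `2i` and `2i + 1`, root at 1), so that during a
#' nearest-spel search every sub-tree whose maximum falls below the current
#' alpha level can be pruned: its alpha-cut is empty.
#'
#' @param image a [fuzzy_image].
#' @param complement build the tree of the complement set (`1 - mu`), needed
#'   for the outward branch of the bidirectional distance.
#' @return An object of class `alpha_tree`.
#' @seealso [mc_point_distance()], [alpha_cut_search()]
#' @export
alpha_tree <- function(image, complement = FALSE) {
  stopifnot(inherits(image, "fuzzy_image"))
  values <- cpp_build_tree(as.numeric(image$mu), as.integer(image$N),
                           image$spacing, complement)
  structure(list(values = values, N = image$N, spacing = image$spacing,
                 complement = complement),
            class = "alpha_tree")
}

#' Object and complement trees of an image
#'
#' Convenience constructor for the pair of trees consumed by
#' [mc_point_distance()].
#'
#' @inheritParams alpha_tree
#' @return list with elements `object` and `complement`.
#' @export
alpha_trees <- function(image) {
  list(object = alpha_tree(image, FALSE),
       complement = alpha_tree(image, TRUE))
}

#' @export
print.alpha_tree <- function(x, ...) {
  cat("<alpha_tree> grid ", paste(x$N, collapse = " x "),
      if (x$complement) " (complement)", ", root max ",
      format(x$values[2]), "\n", sep = "")
  invisible(x)
}

#' Split a grid rectangle for KD-tree construction and search
#'
#' Splits along the physically longest axis, `argmax_k s_k (R_k - 1)`, ties
#' broken by the lowest dimension index; the left half receives
#' `ceiling(R_k / 2)` spels.  Build and search use this same rule so node
#' indices and rectangles stay in correspondence.
#'
#' @param y integer minimal corner (0-based grid coordinates).
#' @param R positive integer rectangle size per dimension.
#' @param spacing spel spacing per dimension.
#' @return list with `left`/`right` (each `y`, `R`) and the split `axis`
#'   (1-based).
#' @export
split_rect <- function(y, R, spacing) {
  res <- cpp_split_rect(as.integer(y), as.integer(R), as.numeric(spacing))
  list(left = list(y = res$y1, R = res$R1),
       right = list(y = res$y2, R = res$R2),
       axis = res$axis)
}

#' Lower bound on the distance from a point to a grid rectangle
#'
#' Euclidean distance from `p` to the nearest spel center of the rectangle:
#' `sqrt(sum(max(0, y_i - p_i, p_i - (y_i + s_i (R_i - 1)))^2))`.  Zero when
#' `p` lies inside the rectangle.
#'
#' @param p physical point.
#' @inheritParams split_rect
#' @return length (numeric scalar).
#' @export
rect_lower_bound <- function(p, y, R, spacing) {
  cpp_rect_lower_bound(as.numeric(p), as.integer(y), as.integer(R),
                       rep_len(as.numeric(spacing), length(p)))
}

#' Relaxed lower bound for approximate pruning
#'
#' Bounds not exceeding the threshold `d_t` are returned exactly; larger
#' bounds are inflated to `d_t + beta * (bound - d_t)`.  With `beta > 1` far
#' sub-trees are pruned more aggressively at the cost of over-estimating far
#' (hence less relevant) distances; `beta = 1` recovers the exact bound.
#'
#' @inheritParams rect_lower_bound
#' @param d_t distance threshold below which the bound stays exact.
#' @param beta relaxation factor, `>= 1`.
#' @export
relaxed_lower_bound <- function(p, y, R, spacing, d_t, beta) {
  stopifnot(beta >= 1, d_t >= 0)
  cpp_relaxed_bound(rect_lower_bound(p, y, R, spacing), d_t, beta)
}

#' Nearest-spel distances above an alpha level via the KD-tree
#'
#' For each corner point, finds `min(d_init, distance to the nearest spel
#' whose stored tree value is >= alpha)`.  Sub-trees are pruned when their
#' maximum falls below `alpha` or when every current corner distance is
#' already below the (relaxed) lower bound of the sub-rectangle; the child
#' rectangle nearer the first corner is visited first.  With `beta = 1` the
#' result is exact.
#'
#' @param corners matrix of corner points (rows; physical grid points).
#' @param alphas one or more levels in (0, 1]; rows of the result.
#' @param tree an [alpha_tree].
#' @param d_init initial (and maximal) distance, recycled to all entries.
#' @param d_t,beta bound relaxation, see [relaxed_lower_bound()].
#' @param joint search all levels in one traversal (identical distances to
#'   the per-level reference path, at lower cost).
#' @return matrix `length(alphas) x nrow(corners)` of distances.
#' @export
alpha_cut_search <- function(corners, alphas, tree, d_init, d_t = 0,
                             beta = 1, joint = TRUE) {
  stopifnot(inherits(tree, "alpha_tree"), all(alphas > 0), all(alphas <= 1))
  corners <- matrix(as.numeric(corners), ncol = length(tree$N))
  ord <- order(alphas)
  d0 <- matrix(as.numeric(d_init), nrow = length(alphas),
               ncol = nrow(corners))
  D <- cpp_alpha_search(corners, as.numeric(alphas[ord]), tree$values,
                        as.integer(tree$N), tree$spacing, d0, d_t, beta,
                        joint)
  D[order(ord), , drop = FALSE]
}

#' Stratified quasi-random alpha levels
#'
#' A 1-D Kronecker sequence at the inverse golden ratio with a random (or
#' supplied) offset: `frac(offset + i / phi_1)`.  Uniform marginally when the
#' offset is uniform, but stratified within each draw, which lowers the
#' variance of the Monte-Carlo distance estimate.  Exact zeros are nudged
#' away since a level-0 cut is the whole domain.
#'
#' @param n_alpha number of levels.
#' @param offset offset in \[0, 1); defaults to a uniform draw from the
#'   session RNG.
#' @return numeric vector of levels in (0, 1).
#' @export
kronecker_alphas <- function(n_alpha, offset = runif(1)) {
  a <- (offset + seq_len(n_alpha) * (golden_ratios(1) %% 1)) %% 1
  a[a == 0] <- .Machine$double.eps
  a
}

# locate the interpolation cell of physical points: 0-based base index,
# fractional offset, and validity (corner cell fully inside the grid)
corner_cell <- function(pts, N, spacing) {
  n <- length(N)
  pts <- matrix(pts, ncol = n)
  t <- sweep(pts, 2, spacing, "/")
  base <- floor(t)
  for (k in seq_len(n)) {
    top <- base[, k] >= N[k] - 1 & t[, k] <= N[k] - 1 + 1e-9
    base[top, k] <- N[k] - 2
    lo <- base[, k] == -1 & t[, k] >= -1e-9
    base[lo, k] <- 0
  }
  u <- t - base
  ok <- rowSums(base < 0 | sweep(base + 1, 2, N - 1, ">")) == 0
  list(base = base, u = u, ok = ok)
}

#' Monte-Carlo estimate of the bidirectional alpha-cut distance
#'
#' Estimates the alpha-averaged point-to-set distance of a fuzzy point
#' (position plus height) to an image, together with its spatial gradient.
#' Each sampled level `alpha <= h(p)` queries the object tree at `alpha`;
#' levels above the height query the complement tree at `1 - alpha`.  Corner
#' distances start at `d_max`, so empty cuts and far structures saturate
#' there.  The per-corner averages are interpolated multilinearly at `p`; the
#' gradient is the discrete derivative of the corner averages, evaluated
#' either at the corner-cell mid-point (default; avoids vanishing derivatives
#' at saddle points of the interpolation surface) or at `p` itself (`stencil
#' = "exact"`, the true derivative of the interpolated distance).
#'
#' @param p physical point (single point; see the batched internal use in
#'   [directed_amd()]).
#' @param height the point's membership height in \[0, 1\].
#' @param trees list with `object` and `complement` [alpha_tree]s, as built
#'   by [alpha_trees()].
#' @param alphas sampled levels in (0, 1), e.g. from [kronecker_alphas()].
#' @param d_max distance truncation.
#' @param d_t,beta bound relaxation of the tree search.
#' @param joint use the joint multi-level traversal.
#' @return list with `value`, `gradient` (both stencils as `grad_mid`,
#'   `grad_exact`), and per-corner distances `corner`.
#' @export
mc_point_distance <- function(p, height, trees, alphas, d_max, d_t = 0,
                              beta = 1, joint = TRUE) {
  res <- mc_point_distances(matrix(p, nrow = 1), height, trees, alphas,
                            d_max, d_t, beta, joint)
  if (!res$indomain[1])
    stop("point is outside the interpolation-valid region of the grid")
  list(value = res$value[1],
       grad_mid = res$grad_mid[1, ], grad_exact = res$grad_exact[1, ],
       corner = res$corner[1, ])
}

# batched estimator; out-of-domain points get indomain = FALSE and NA values
mc_point_distances <- function(pts, heights, trees, alphas, d_max, d_t = 0,
                               beta = 1, joint = TRUE) {
  tS <- trees$object
  tC <- trees$complement
  cpp_mc_distance(matrix(as.numeric(pts), ncol = length(tS$N)),
                  rep_len(as.numeric(heights), nrow(matrix(pts, ncol = length(tS$N)))),
                  tS$values, tC$values, as.integer(tS$N), tS$spacing,
                  as.numeric(alphas), d_max, d_t, beta, joint)
}

#' Brute-force alpha-cut distance (test oracle)
#'
#' Same quadrature as [mc_point_distance()] — the given alpha levels are
#' averaged with equal weight at the corner grid points and interpolated at
#' `p` — but every nearest-spel query is an exhaustive linear scan over the
#' grid.  Exists as an independent reference for the tree-based estimator.
#'
#' @inheritParams mc_point_distance
#' @param image the [fuzzy_image] (the set `S`).
#' @return list with `value` and per-corner distances `corner`.
#' @export
exact_alpha_distance <- function(p, height, image, alphas, d_max) {
  cc <- corner_cell(p, image$N, image$spacing)
  if (!cc$ok[1])
    stop("point is outside the interpolation-valid region of the grid")
  n <- length(image$N)
  ncorner <- 2^n
  offs <- as.matrix(expand.grid(rep(list(0:1), n)))
  corners <- sweep(sweep(offs, 2, cc$base[1, ], "+"), 2, image$spacing, "*")
  pos <- spel_position(as.matrix(expand.grid(lapply(image$N, seq_len))),
                       image$spacing)
  mu <- as.numeric(image$mu)
  D <- matrix(0, length(alphas), ncorner)
  for (ia in seq_along(alphas)) {
    a <- alphas[ia]
    sel <- if (a <= height) mu >= a else (1 - mu) >= (1 - a)
    for (j in seq_len(ncorner)) {
      if (!any(sel)) { D[ia, j] <- d_max; next }
      d2 <- rowSums(sweep(pos[sel, , drop = FALSE], 2, corners[j, ], "-")^2)
      D[ia, j] <- min(sqrt(min(d2)), d_max)
    }
  }
  corner <- colMeans(D)
  u <- cc$u[1, ]
  w <- apply(offs, 1, function(o) prod(ifelse(o == 1, u, 1 - u)))
  list(value = sum(w * corner), corner = corner)
}

#' Exact level-set quadrature of the bidirectional distance
#'
#' Closed-form evaluation of the alpha integral with distances truncated at
#' `d_max`: the distance to an alpha-cut is piecewise constant in alpha with
#' breakpoints at the distinct membership values, so the integral is a finite
#' weighted sum of exhaustive nearest-spel scans.  This is the expectation of
#' the Monte-Carlo estimator under uniform alpha sampling.
#'
#' @inheritParams exact_alpha_distance
#' @return the interpolated distance value at `p`.
#' @export
exact_alpha_quadrature <- function(p, height, image, d_max) {
  cc <- corner_cell(p, image$N, image$spacing)
  if (!cc$ok[1])
    stop("point is outside the interpolation-valid region of the grid")
  n <- length(image$N)
  offs <- as.matrix(expand.grid(rep(list(0:1), n)))
  corners <- sweep(sweep(offs, 2, cc$base[1, ], "+"), 2, image$spacing, "*")
  pos <- spel_position(as.matrix(expand.grid(lapply(image$N, seq_len))),
                       image$spacing)
  mu <- as.numeric(image$mu)

  piecewise <- function(values, upper) {
    # integral over alpha in (0, upper] of dist(p, {values >= alpha})
    lev <- sort(unique(values))
    out <- numeric(2^n)
    lo <- 0
    for (l in c(lev[lev > 0], Inf)) {
      hi <- min(l, upper)
      if (hi <= lo) break
      sel <- if (is.infinite(l)) rep(FALSE, length(values)) else values >= l
      for (j in seq_len(2^n)) {
        d <- if (!any(sel)) d_max else
          min(sqrt(min(rowSums(sweep(pos[sel, , drop = FALSE], 2,
                                     corners[j, ], "-")^2))), d_max)
        out[j] <- out[j] + (hi - lo) * d
      }
      lo <- hi
      if (lo >= upper) break
    }
    out
  }
  corner <- piecewise(mu, height) + piecewise(1 - mu, 1 - height)
  u <- cc$u[1, ]
  w <- apply(offs, 1, function(o) prod(ifelse(o == 1, u, 1 - u)))
  sum(w * corner)
}
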