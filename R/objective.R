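#' Monte-Carlo distance configuration
#'
#' Bundles the knobs of the alpha-cut distance estimator used inside the
#' registration objective.
#'
#' @param n_alpha number of alpha samples per evaluation.
#' @param d_max distance truncation (physical length; schedules specify it
#'   as a fraction of the image diameter).
#' @param d_t,beta bound relaxation of the tree search
#'   ([relaxed_lower_bound()]); `beta = 1` keeps the search exact.
#' @param joint single-traversal multi-level search.
#' @param stencil gradient stencil of the interpolated distance surface:
#'   `"midpoint"` (cell mid-point; robust against saddle points, the
#'   optimization default) or `"exact"` (derivative at the point itself,
#'   used for finite-difference verification).
#' @param alphas explicit alpha levels; when `NULL` a fresh stratified set
#'   is drawn per objective evaluation via [kronecker_alphas()].
#' @return list of class `mc_config`.
#' @export
mc_config <- function(n_alpha = 7, d_max, d_t = 0, beta = 1, joint = TRUE,
                      stencil = c("midpoint", "exact"), alphas = NULL) {
  stencil <- match.arg(stencil)
  stopifnot(n_alpha >= 1, d_max > 0, beta >= 1, d_t >= 0)
  structure(list(n_alpha = n_alpha, d_max = d_max, d_t = d_t, beta = beta,
                 joint = joint, stencil = stencil, alphas = alphas),
            class = "mc_config")
}

#' Transformation pair with regularization weight
#'
#' Holds the two directed B-spline transformations (`T_AB` maps
#' floating-image coordinates into reference space, `T_BA` the reverse) and
#' the inverse-inconsistency weight `lambda`.
#'
#' @param T_AB,T_BA [bspline_field]s.
#' @param lambda regularization weight, `>= 0`.
#' @return list of class `objective_pair`.
#' @export
objective_pair <- function(T_AB, T_BA, lambda = 0) {
  stopifnot(inherits(T_AB, "bspline_field"), inherits(T_BA, "bspline_field"),
            lambda >= 0)
  structure(list(T_AB = T_AB, T_BA = T_BA, lambda = lambda),
            class = "objective_pair")
}

# shared kept-point rule: transformed point has a valid interpolation cell
# in the target grid and lies inside the target mask (if any)
kept_points <- function(y, target) {
  corner_cell(y, target$N, target$spacing)$ok & in_mask(y, target)
}

#' Directed alpha-averaged minimal distance between images
#'
#' Transforms a sampled set of fuzzy points of the source image by `T`,
#' keeps those landing inside the target mask (and grid), and returns the
#' weight-normalized mean of their Monte-Carlo alpha-cut distances to the
#' target, together with the ingredients for back-propagation: per-point
#' spatial gradients and the raw (unnormalized) chain-rule gradient with
#' respect to the control parameters of `T`.
#'
#' @param points sample set as returned by [draw_points()]: list with `pos`
#'   (physical positions), `height` (memberships carried as fuzzy-point
#'   heights; no intensity interpolation is performed) and `weight`.
#' @param transform the directed [bspline_field] `T`.
#' @param trees [alpha_trees()] of the target image.
#' @param target the target [fuzzy_image] (supplies grid and mask).
#' @param mc_cfg an [mc_config]; `mc_cfg$alphas` must be set.
#' @return list with `value`, `kept` (logical per input point), `w_sum`,
#'   `y` (transformed positions), `point_grad` (spatial gradients at kept
#'   points, chosen stencil) and `ctrl_grad_raw` (`nctrl x n`, the sum
#'   `sum_x w(x) g(T(x)) dT(x)/dPhi` without weight normalization).
#' @export
directed_amd <- function(points, transform, trees, target, mc_cfg) {
  stopifnot(length(points$height) == nrow(points$pos))
  y <- transform_points(transform, points$pos)
  mc <- mc_point_distances(y, points$height, trees, mc_cfg$alphas,
                           mc_cfg$d_max, mc_cfg$d_t, mc_cfg$beta,
                           mc_cfg$joint)
  kept <- mc$indomain & in_mask(y, target)
  if (!any(kept))
    stop("no overlap: no sampled point lands inside the target mask")
  w <- points$weight[kept]
  w_sum <- sum(w)
  value <- sum(w * mc$value[kept]) / w_sum
  g <- if (mc_cfg$stencil == "exact") mc$grad_exact else mc$grad_mid
  g <- g[kept, , drop = FALSE]
  jac <- param_jacobian(transform, points$pos[kept, , drop = FALSE])
  ctrl_grad_raw <- cpp_accum_ctrl(jac$idx, jac$w, g * w,
                                  nrow(transform$phi))
  list(value = value, kept = kept, w_sum = w_sum, y = y,
       point_grad = g, ctrl_grad_raw = ctrl_grad_raw)
}

#' Pointwise inverse inconsistency
#'
#' Half the squared norm of the round-trip residual,
#' `0.5 * ||T_BA(T_AB(x)) - x||^2`; zero exactly when the two
#' transformations invert each other at `x`.
#'
#' @param T_AB,T_BA [bspline_field]s.
#' @param x physical point(s), rows.
#' @return numeric vector of inconsistency values.
#' @export
point_iic <- function(T_AB, T_BA, x) {
  x <- matrix(as.numeric(x), ncol = length(T_AB$counts))
  r <- compose_points(T_BA, T_AB, x) - x
  0.5 * rowSums(r^2)
}

#' Average weighted inverse inconsistency with gradients
#'
#' Weight-normalized mean of [point_iic()] over the sample points whose
#' forward image lands inside the target mask, with raw chain-rule
#' gradients with respect to both transformations.  The outer field's
#' parameter Jacobian is evaluated at the composed location; the inner
#' field's contribution passes through the outer field's analytic spatial
#' derivative.
#'
#' @param T_fwd,T_bwd forward (inner) and backward (outer) [bspline_field]s.
#' @param points sample set in the forward field's source space (list with
#'   `pos` and `weight`).
#' @param target the [fuzzy_image] whose grid/mask gates the kept set.
#' @return list with `value`, `kept`, `w_sum`, and raw gradients
#'   `grad_fwd_raw` / `grad_bwd_raw` (`nctrl x n`, unnormalized).  An empty
#'   kept set yields value 0 and zero gradients (with a message).
#' @export
aw_iic <- function(T_fwd, T_bwd, points, target) {
  x <- points$pos
  y <- transform_points(T_fwd, x)
  kept <- kept_points(y, target)
  n <- ncol(x)
  if (!any(kept)) {
    message("aw_iic: empty kept set; contributing 0")
    z <- matrix(0, nrow(T_fwd$phi), n)
    z2 <- matrix(0, nrow(T_bwd$phi), n)
    return(list(value = 0, kept = kept, w_sum = 0,
                grad_fwd_raw = z, grad_bwd_raw = z2))
  }
  xk <- x[kept, , drop = FALSE]
  yk <- y[kept, , drop = FALSE]
  w <- points$weight[kept]
  w_sum <- sum(w)
  zk <- transform_points(T_bwd, yk)
  r <- zk - xk
  value <- sum(w * 0.5 * rowSums(r^2)) / w_sum
  # outer (backward) field: dIIC/dPhi_bwd = w * r * B(y)
  jac_out <- param_jacobian(T_bwd, yk)
  grad_bwd_raw <- cpp_accum_ctrl(jac_out$idx, jac_out$w, r * w,
                                 nrow(T_bwd$phi))
  # inner (forward) field: residual passed through the outer spatial
  # Jacobian, dIIC/dPhi_fwd = w * (J_bwd^T r) * B(x)
  J <- field_spatial_jacobian(T_bwd, yk)
  Jt_r <- matrix(0, nrow(yk), n)
  for (comp in seq_len(n))
    Jt_r[, comp] <- rowSums(r * J[, , comp, drop = FALSE][, , 1])
  jac_in <- param_jacobian(T_fwd, xk)
  grad_fwd_raw <- cpp_accum_ctrl(jac_in$idx, jac_in$w, Jt_r * w,
                                 nrow(T_fwd$phi))
  list(value = value, kept = kept, w_sum = w_sum,
       grad_fwd_raw = grad_fwd_raw, grad_bwd_raw = grad_bwd_raw)
}

#' Symmetric registration objective with gradients
#'
#' Assembles the full objective
#' `J = (d_AB + d_BA) / 2 + lambda * (iic_AB + iic_BA) / 2`
#' from the two directed distance terms and the two inverse-inconsistency
#' terms, each direction evaluated on its own sample set, plus the
#' gradients with respect to both control-parameter vectors (normalized,
#' i.e. the true gradient of `J`) and the raw unnormalized gradients used
#' by the scaled stochastic optimizer.
#'
#' @param pair an [objective_pair].
#' @param A,B floating and reference [fuzzy_image]s (the level images).
#' @param trees_A,trees_B [alpha_trees()] of `A` and `B`.
#' @param P_A,P_B sample sets from [draw_points()] on `A` and `B`.
#' @param mc_cfg an [mc_config]; when its `alphas` slot is `NULL` a fresh
#'   stratified level set is drawn here and shared by both directions.
#' @return list of class `objective_report`: `J`, `components` (named
#'   `d_AB`, `d_BA`, `iic_AB`, `iic_BA`), `grad_AB`, `grad_BA`
#'   (gradients of `J`), `raw_grad_AB`, `raw_grad_BA` (unnormalized),
#'   and kept counts `n_A`, `n_B`.
#' @export
total_objective <- function(pair, A, B, trees_A, trees_B, P_A, P_B, mc_cfg) {
  stopifnot(inherits(pair, "objective_pair"))
  if (is.null(mc_cfg$alphas))
    mc_cfg$alphas <- kronecker_alphas(mc_cfg$n_alpha)
  lambda <- pair$lambda

  d_ab <- directed_amd(P_A, pair$T_AB, trees_B, B, mc_cfg)
  d_ba <- directed_amd(P_B, pair$T_BA, trees_A, A, mc_cfg)
  i_ab <- aw_iic(pair$T_AB, pair$T_BA, P_A, B)
  i_ba <- aw_iic(pair$T_BA, pair$T_AB, P_B, A)

  J <- 0.5 * (d_ab$value + d_ba$value) +
    lambda / 2 * (i_ab$value + i_ba$value)

  norm0 <- function(g, w) if (w > 0) g / w else g
  grad_AB <- 0.5 * d_ab$ctrl_grad_raw / d_ab$w_sum +
    lambda / 2 * (norm0(i_ab$grad_fwd_raw, i_ab$w_sum) +
                  norm0(i_ba$grad_bwd_raw, i_ba$w_sum))
  grad_BA <- 0.5 * d_ba$ctrl_grad_raw / d_ba$w_sum +
    lambda / 2 * (norm0(i_ba$grad_fwd_raw, i_ba$w_sum) +
                  norm0(i_ab$grad_bwd_raw, i_ab$w_sum))
  raw_grad_AB <- 0.5 * d_ab$ctrl_grad_raw +
    lambda / 2 * (i_ab$grad_fwd_raw + i_ba$grad_bwd_raw)
  raw_grad_BA <- 0.5 * d_ba$ctrl_grad_raw +
    lambda / 2 * (i_ba$grad_fwd_raw + i_ab$grad_bwd_raw)

  structure(
    list(J = J,
         components = c(d_AB = d_ab$value, d_BA = d_ba$value,
                        iic_AB = i_ab$value, iic_BA = i_ba$value),
         grad_AB = grad_AB, grad_BA = grad_BA,
         raw_grad_AB = raw_grad_AB, raw_grad_BA = raw_grad_BA,
         n_A = sum(d_ab$kept), n_B = sum(d_ba$kept),
         alphas = mc_cfg$alphas),
    class = "objective_report")
}

#' @export
print.objective_report <- function(x, ...) {
  cat("<objective_report> J = ", format(x$J, digits = 6), "\n  components: ",
      paste(names(x$components), format(x$components, digits = 4),
            sep = " = ", collapse = ", "),
      "\n  kept points: ", x$n_A, " (A), ", x$n_B, " (B)\n", sep = "")
  invisible(x)
}
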