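#' State of the momentum optimizer for one transformation
#'
#' Classic heavy-ball stochastic gradient descent: per-parameter velocity,
#' step size, momentum, and the floor constant `eps` that keeps the
#' derivative scaling finite for parameters whose support contains no
#' sampled point.
#'
#' @param n_ctrl,n_dim control-mesh size (rows) and dimensionality.
#' @param step_size positive step size `eta` (physical length scale).
#' @param momentum momentum `mu` in \[0, 1).
#' @param eps scaling floor (default 0.01).
#' @return list of class `sgdm_state`.
#' @export
sgdm_state <- function(n_ctrl, n_dim, step_size, momentum, eps = 0.01) {
  stopifnot(step_size > 0, momentum >= 0, momentum < 1, eps > 0)
  structure(list(v = matrix(0, n_ctrl, n_dim), step_size = step_size,
                 momentum = momentum, eps = eps),
            class = "sgdm_state")
}

#' Per-parameter derivative scaling factors
#'
#' The scaling factor of a parameter measures its total impact on the
#' transformation of the sampled points: for a parameter of `T_AB` it is
#' the weighted sum of its basis weights over the kept points of `P_A`,
#' plus `lambda` times the norms of its derivative through the round-trip
#' compositions in both directions.  Dividing the raw gradient by
#' `gamma + eps` makes the update magnitude largely independent of mesh
#' coarseness and of how many points happen to fall inside a parameter's
#' support.
#'
#' @param pair an [objective_pair].
#' @param P_A,P_B sample sets ([draw_points()]) in the two image domains.
#' @param A,B the two [fuzzy_image]s (grids/masks gate the kept sets).
#' @return list with matrices `gamma_AB` and `gamma_BA` (`nctrl x n`,
#'   matching the layout of the control meshes).
#' @export
scale_factor <- function(pair, P_A, P_B, A, B) {
  lambda <- pair$lambda
  n <- length(pair$T_AB$counts)

  one_direction <- function(T_fwd, T_bwd, P_f, P_b, tgt_f, tgt_b) {
    # gamma for the parameters of T_fwd
    y_f <- transform_points(T_fwd, P_f$pos)
    kf <- kept_points(y_f, tgt_f)
    xk <- P_f$pos[kf, , drop = FALSE]
    wk <- P_f$weight[kf]
    jac <- param_jacobian(T_fwd, xk)
    nctrl <- nrow(T_fwd$phi)
    t1 <- cpp_accum_ctrl(jac$idx, jac$w, matrix(wk, ncol = 1), nctrl)
    gamma <- matrix(t1, nctrl, n)
    if (lambda > 0) {
      # through T_bwd(T_fwd(x)): column norms of the outer spatial Jacobian
      J <- field_spatial_jacobian(T_bwd, y_f[kf, , drop = FALSE])
      cn <- sqrt(apply(J^2, c(1, 3), sum))  # npts x n, norm per column
      gamma <- gamma + lambda *
        cpp_accum_ctrl(jac$idx, jac$w, cn * wk, nctrl)
      # through T_fwd(T_bwd(x)) for x in the other domain: T_fwd is outer
      y_b <- transform_points(T_bwd, P_b$pos)
      kb <- kept_points(y_b, tgt_b)
      if (any(kb)) {
        jac_o <- param_jacobian(T_fwd, y_b[kb, , drop = FALSE])
        gamma <- gamma + lambda * matrix(
          cpp_accum_ctrl(jac_o$idx, jac_o$w,
                         matrix(P_b$weight[kb], ncol = 1), nctrl),
          nctrl, n)
      }
    }
    gamma
  }
  list(gamma_AB = one_direction(pair$T_AB, pair$T_BA, P_A, P_B, B, A),
       gamma_BA = one_direction(pair$T_BA, pair$T_AB, P_B, P_A, A, B))
}

#' One scaled heavy-ball update
#'
#' `v <- momentum * v - step_size * g / (gamma + eps)`;
#' `phi <- phi + v`.
#'
#' @param state an [sgdm_state].
#' @param phi control-displacement matrix.
#' @param grad raw gradient matrix (same shape as `phi`).
#' @param gamma scaling factors (same shape; 0 allowed).
#' @return list with updated `state` and `phi`.
#' @export
sgdm_step <- function(state, phi, grad, gamma) {
  stopifnot(identical(dim(phi), dim(grad)), identical(dim(phi), dim(gamma)))
  state$v <- state$momentum * state$v -
    state$step_size * grad / (gamma + state$eps)
  list(state = state, phi = phi + state$v)
}

#' Run one optimization stage
#'
#' Iterates draw points -> evaluate objective -> scale -> update for one
#' level of the coarse-to-fine schedule, updating both directed
#' transformations jointly each iteration from the same objective report.
#' Velocities start at zero (fresh optimizer state per stage).  Iterations
#' whose sample produces no overlap between the images are skipped; ten
#' consecutive failures abort the stage.
#'
#' @param A,B floating and reference level [fuzzy_image]s.
#' @param trees_A,trees_B [alpha_trees()] of the level images.
#' @param pair an [objective_pair]; its fields must already have the
#'   level's control counts.
#' @param level one level record of a [stage_schedule] (list with
#'   `iterations`, `sampling_fraction`, `d_max_per_diameter`, `step_size`,
#'   `momentum`, `gw_m`, `gw_sigma`).
#' @param globals schedule globals (list with `lambda`, `n_alpha`, `beta`,
#'   `d_t`, optional `t_gm`).
#' @param stencil distance-gradient stencil, see [mc_config()].
#' @return list with the updated `pair` and a `trace` data frame
#'   (iteration, J and its four components).
#' @export
run_stage <- function(A, B, trees_A, trees_B, pair, level, globals,
                      stencil = "midpoint") {
  iters <- level$iterations
  trace <- data.frame(iteration = integer(0), J = numeric(0),
                      d_AB = numeric(0), d_BA = numeric(0),
                      iic_AB = numeric(0), iic_BA = numeric(0))
  if (iters < 1) return(list(pair = pair, trace = trace))

  d_max <- level$d_max_per_diameter * image_extent(B)$diameter
  t_gm <- if (is.null(globals$t_gm)) 0 else globals$t_gm
  cfg <- sampler_config(m = level$gw_m, sigma_gm = level$gw_sigma,
                        t_gm = t_gm, fraction = level$sampling_fraction)
  map_A <- if (cfg$m > 0) gradient_weight_map(A, cfg$sigma_gm, t_gm)
  map_B <- if (cfg$m > 0) gradient_weight_map(B, cfg$sigma_gm, t_gm)
  n_A <- max(1L, round(cfg$fraction * prod(A$N)))
  n_B <- max(1L, round(cfg$fraction * prod(B$N)))

  st_AB <- sgdm_state(nrow(pair$T_AB$phi), length(A$N),
                      level$step_size, level$momentum)
  st_BA <- sgdm_state(nrow(pair$T_BA$phi), length(A$N),
                      level$step_size, level$momentum)
  base_cfg <- mc_config(n_alpha = globals$n_alpha, d_max = d_max,
                        d_t = globals$d_t, beta = globals$beta,
                        stencil = stencil)
  fails <- 0L
  trace <- vector("list", iters)
  for (it in seq_len(iters)) {
    cfg_it <- base_cfg
    cfg_it$alphas <- kronecker_alphas(globals$n_alpha)
    P_A <- draw_points(A, n_A, cfg, map_A)
    P_B <- draw_points(B, n_B, cfg, map_B)
    rep <- tryCatch(
      total_objective(pair, A, B, trees_A, trees_B, P_A, P_B, cfg_it),
      error = function(e) {
        if (grepl("no overlap", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(rep)) {
      fails <- fails + 1L
      if (fails >= 10L)
        stop("stage aborted: no overlap between the images in 10 ",
             "consecutive iterations")
      next
    }
    fails <- 0L
    if (!is.finite(rep$J) || !all(is.finite(rep$raw_grad_AB)) ||
        !all(is.finite(rep$raw_grad_BA)))
      stop("non-finite objective or gradient at iteration ", it)
    gam <- scale_factor(pair, P_A, P_B, A, B)
    up <- sgdm_step(st_AB, pair$T_AB$phi, rep$raw_grad_AB, gam$gamma_AB)
    st_AB <- up$state
    pair$T_AB$phi <- up$phi
    up <- sgdm_step(st_BA, pair$T_BA$phi, rep$raw_grad_BA, gam$gamma_BA)
    st_BA <- up$state
    pair$T_BA$phi <- up$phi
    trace[[it]] <- c(it, rep$J, rep$components)
  }
  trace <- do.call(rbind, trace)
  trace <- as.data.frame(trace)
  names(trace) <- c("iteration", "J", "d_AB", "d_BA", "iic_AB", "iic_BA")
  list(pair = pair, trace = trace)
}
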