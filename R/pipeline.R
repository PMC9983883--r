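#' Robust normalization and optional histogram equalization
#'
#' Clips intensities at the `q` and `100 - q` percentiles, rescales to
#' \[0, 1\], and optionally equalizes the histogram with the configured bin
#' count.  This removes differences in value range and outliers between the
#' images to be registered.  A constant (degenerate-range) image maps to
#' constant 0 with a message.
#'
#' @param values numeric matrix or 3D array of raw intensities.
#' @param q clipping percentile in \[0, 50), in percent (e.g. `0.025`).
#' @param histeq apply histogram equalization after normalization.
#' @param bins number of equalization bins.
#' @return array of memberships in \[0, 1\] (same shape).
#' @export
preprocess_image <- function(values, q = 0, histeq = FALSE, bins = 256) {
  stopifnot(q >= 0, q < 50)
  lo <- quantile(values, q / 100, names = FALSE, na.rm = TRUE)
  hi <- quantile(values, 1 - q / 100, names = FALSE, na.rm = TRUE)
  if (hi <= lo) {
    message("preprocess_image: degenerate intensity range; returning 0")
    return(array(0, dim = dim(values)))
  }
  out <- pmin(pmax(values, lo), hi)
  out <- (out - lo) / (hi - lo)
  if (histeq) {
    bin <- pmin(floor(out * bins) + 1L, bins)
    h <- tabulate(bin, nbins = bins)
    cdf <- cumsum(h) / sum(h)
    out <- array(cdf[bin], dim = dim(values))
  }
  array(out, dim = dim(values))
}

#' Stage schedule for coarse-to-fine registration
#'
#' An ordered set of per-level records plus global constants.  Levels run
#' coarse to fine: subsampling factors are relative to the original
#' resolution and non-increasing, control counts non-decreasing.
#'
#' @param levels data frame with one row per level and columns
#'   `subsampling_factor`, `sigma`, `control_points`, `iterations`,
#'   `sampling_fraction`, `d_max_per_diameter`, `step_size`, `momentum`,
#'   `gw_m`, `gw_sigma`.
#' @param lambda inverse-inconsistency weight.
#' @param n_alpha alpha samples per objective evaluation.
#' @param q normalization percentile (percent).
#' @param histeq,histeq_bins histogram-equalization switch and bin count.
#' @param beta,d_t KD-tree search relaxation constants.
#' @param t_gm gradient-magnitude threshold of the point sampler.
#' @return list of class `stage_schedule`.
#' @export
stage_schedule <- function(levels, lambda = 0.005, n_alpha = 7, q = 0,
                           histeq = FALSE, histeq_bins = 256, beta = 1.2,
                           d_t = 20, t_gm = 0) {
  need <- c("subsampling_factor", "sigma", "control_points", "iterations",
            "sampling_fraction", "d_max_per_diameter", "step_size",
            "momentum", "gw_m", "gw_sigma")
  missing_cols <- setdiff(need, names(levels))
  if (length(missing_cols))
    stop("schedule levels lack columns: ", paste(missing_cols, collapse = ", "))
  if (any(levels$subsampling_factor < 1))
    stop("subsampling factors must be >= 1")
  if (is.unsorted(rev(levels$subsampling_factor)))
    stop("levels must run coarse to fine (non-increasing subsampling)")
  if (is.unsorted(levels$control_points))
    stop("control counts must be non-decreasing")
  structure(list(levels = as.data.frame(levels), lambda = lambda,
                 n_alpha = n_alpha, q = q, histeq = histeq,
                 histeq_bins = histeq_bins, beta = beta, d_t = d_t,
                 t_gm = t_gm),
            class = "stage_schedule")
}

#' Load a stage schedule from JSON
#'
#' The file holds the global constants at top level and a `levels` array of
#' per-level records, mirroring the shipped presets under
#' `system.file("schedules", package = "alphareg")`.
#'
#' @param path JSON file path.
#' @return a [stage_schedule].
#' @export
load_schedule <- function(path) {
  js <- jsonlite::fromJSON(path)
  stage_schedule(levels = js$levels,
                 lambda = js$lambda, n_alpha = js$n_alpha, q = js$q,
                 histeq = isTRUE(js$histeq),
                 histeq_bins = if (is.null(js$histeq_bins)) 256
                               else js$histeq_bins,
                 beta = js$beta, d_t = js$d_t,
                 t_gm = if (is.null(js$t_gm)) 0 else js$t_gm)
}

#' Shipped schedule presets
#'
#' `"retinal-synthetic"`, `"fire"` and `"brain-mri"` are reference
#' configurations for large fundus images and 3D brain MR volumes; `"phantom-128"` is a three-level schedule sized for the 128 px
#' vessel phantoms of [make_vessel_phantom()].
#'
#' @param name preset name.
#' @return a [stage_schedule].
#' @export
schedule_preset <- function(name = c("phantom-128", "retinal-synthetic",
                                     "fire", "brain-mri")) {
  name <- match.arg(name)
  load_schedule(system.file("schedules", paste0(name, ".json"),
                            package = "alphareg", mustWork = TRUE))
}

#' Gaussian resolution pyramid
#'
#' Per level: Gaussian smoothing with the level's `sigma` (in spels of the
#' input; `sigma = 0` skips smoothing) followed by block-mean downsampling
#' by the level's subsampling factor (relative to the original image).
#' Physical spacing scales with the factor, so all levels live in the same
#' physical frame.  Masks are downsampled by majority vote, weights by
#' block mean.
#'
#' @param image a [fuzzy_image] at full resolution.
#' @param schedule a [stage_schedule].
#' @return list of per-level [fuzzy_image]s.
#' @export
build_pyramid <- function(image, schedule) {
  lapply(seq_len(nrow(schedule$levels)), function(i) {
    lv <- schedule$levels[i, ]
    f <- as.integer(lv$subsampling_factor)
    mu <- if (lv$sigma > 0)
      cpp_gauss_filter(as.numeric(image$mu), as.integer(image$N),
                       lv$sigma, -1L)
    else as.numeric(image$mu)
    mu <- pmin(pmax(mu, 0), 1)
    N <- image$N
    if (f > 1) {
      keep <- (N %/% f) * f
      mu <- array(mu, dim = N)
      mu <- do.call(`[`, c(list(mu), lapply(keep, seq_len), drop = FALSE))
      mu <- cpp_block_mean(as.numeric(mu), as.integer(keep), f)
    }
    dims <- if (f > 1) N %/% f else N
    mask <- image$mask
    if (!is.null(mask) && f > 1) {
      m <- do.call(`[`, c(list(array(as.numeric(mask), dim = N)),
                          lapply((N %/% f) * f, seq_len), drop = FALSE))
      mask <- array(cpp_block_mean(as.numeric(m),
                                   as.integer((N %/% f) * f), f) > 0.5,
                    dim = dims)
    }
    wts <- image$weights
    if (!is.null(wts) && f > 1) {
      w <- do.call(`[`, c(list(array(wts, dim = N)),
                          lapply((N %/% f) * f, seq_len), drop = FALSE))
      wts <- array(cpp_block_mean(as.numeric(w),
                                  as.integer((N %/% f) * f), f),
                   dim = dims)
    }
    fuzzy_image(array(mu, dim = dims), spacing = image$spacing * f,
                mask = mask, weights = wts)
  })
}

#' Symmetric deformable registration of an image pair
#'
#' Runs the full coarse-to-fine pipeline: preprocessing, Gaussian pyramids,
#' per-level KD-trees, stage-to-stage B-spline refinement and stochastic
#' optimization of the symmetric objective.  Following the floating/
#' reference convention, `T_AB` maps floating-image coordinates into
#' reference space and `T_BA` the reverse.
#'
#' @param ref,flo reference and floating images: [fuzzy_image]s (used
#'   as-is) or raw numeric arrays (preprocessed with the schedule's
#'   normalization settings).
#' @param schedule a [stage_schedule].
#' @param seed optional integer seed; fixing it makes the whole run
#'   deterministic.
#' @param ref_mask,flo_mask optional logical masks (only used for raw array
#'   inputs; fuzzy images carry their own).
#' @param stencil distance-gradient stencil, see [mc_config()].
#' @param verbose print per-level progress.
#' @return list of class `registration_result` with `T_AB`, `T_BA`,
#'   `trace` (per-iteration objective values with a `level` column) and
#'   the `schedule`.
#' @export
register_images <- function(ref, flo, schedule, seed = NULL,
                            ref_mask = NULL, flo_mask = NULL,
                            stencil = "midpoint", verbose = FALSE) {
  stopifnot(inherits(schedule, "stage_schedule"))
  if (!is.null(seed)) set.seed(seed)
  as_fuzzy <- function(x, mask) {
    if (inherits(x, "fuzzy_image")) return(x)
    fuzzy_image(preprocess_image(x, q = schedule$q,
                                 histeq = schedule$histeq,
                                 bins = schedule$histeq_bins),
                mask = mask)
  }
  B <- as_fuzzy(ref, ref_mask)   # reference
  A <- as_fuzzy(flo, flo_mask)   # floating
  if (length(A$N) != length(B$N))
    stop("reference and floating images must share dimensionality")
  n <- length(A$N)
  pyr_A <- build_pyramid(A, schedule)
  pyr_B <- build_pyramid(B, schedule)
  globals <- schedule[c("lambda", "n_alpha", "beta", "d_t", "t_gm")]
  ext_A <- image_extent(A)$extent
  ext_B <- image_extent(B)$extent

  pair <- NULL
  traces <- list()
  for (i in seq_len(nrow(schedule$levels))) {
    lv <- schedule$levels[i, ]
    cc <- rep(as.integer(lv$control_points), n)
    if (is.null(pair)) {
      pair <- objective_pair(bspline_field(cc, ext_A),
                             bspline_field(cc, ext_B),
                             lambda = schedule$lambda)
    } else {
      pair$T_AB <- refine(pair$T_AB, cc)
      pair$T_BA <- refine(pair$T_BA, cc)
    }
    Al <- pyr_A[[i]]
    Bl <- pyr_B[[i]]
    trees_A <- alpha_trees(Al)
    trees_B <- alpha_trees(Bl)
    if (verbose)
      message(sprintf("level %d: %s px, %d controls, %d iterations", i,
                      paste(Al$N, collapse = "x"), lv$control_points,
                      lv$iterations))
    res <- run_stage(Al, Bl, trees_A, trees_B, pair, as.list(lv), globals,
                     stencil = stencil)
    pair <- res$pair
    if (nrow(res$trace)) res$trace$level <- i
    traces[[i]] <- res$trace
  }
  structure(list(T_AB = pair$T_AB, T_BA = pair$T_BA,
                 trace = do.call(rbind, traces), schedule = schedule),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> ", nrow(x$schedule$levels), " levels, final J = ",
      format(utils::tail(x$trace$J, 1), digits = 5), "\n", sep = "")
  invisible(x)
}

# multilinear or nearest interpolation of an array at physical points;
# outside the grid -> `fill`
interp_at <- function(values, spacing, pts, method = "linear", fill = 0) {
  N <- dim(values)
  n <- length(N)
  npts <- nrow(pts)
  out <- rep(fill, npts)
  if (method == "nearest") {
    idx <- round(sweep(pts, 2, spacing, "/")) + 1
    ok <- rowSums(idx < 1 | sweep(idx, 2, N, ">")) == 0
    if (any(ok))
      out[ok] <- values[linear_index(idx[ok, , drop = FALSE], N)]
    return(out)
  }
  cc <- corner_cell(pts, N, spacing)
  ok <- cc$ok
  if (!any(ok)) return(out)
  base <- cc$base[ok, , drop = FALSE]
  u <- cc$u[ok, , drop = FALSE]
  offs <- as.matrix(expand.grid(rep(list(0:1), n)))
  acc <- 0
  for (j in seq_len(nrow(offs))) {
    idx <- sweep(base, 2, offs[j, ], "+") + 1
    w <- rep(1, nrow(base))
    for (k in seq_len(n))
      w <- w * (if (offs[j, k] == 1) u[, k] else 1 - u[, k])
    acc <- acc + w * values[linear_index(idx, N)]
  }
  out[ok] <- acc
  out
}

#' Resample an image through a transformation (pull-back warping)
#'
#' Renders the source image on the target grid by sampling it at the
#' transformed position of each target grid point: to put the floating
#' image onto the reference grid, pass `field = T_BA` (the map from
#' reference coordinates into floating space).  Intensities use linear
#' interpolation; masks and label maps should use `"nearest"`.
#'
#' @param image source [fuzzy_image], or a numeric/logical/integer array
#'   (assumed on a unit-spacing grid).
#' @param field the [bspline_field] mapping target coordinates into the
#'   source space.
#' @param target grid definition (a [fuzzy_image] or a list with `N` and
#'   `spacing`); defaults to the source grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill value for target points mapping outside the source grid.
#' @return array on the target grid.
#' @export
warp_image <- function(image, field, target = NULL,
                       interpolation = c("linear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  if (!inherits(image, "fuzzy_image")) {
    vals <- image
    spacing <- rep(1, length(dim(vals)))
  } else {
    vals <- image$mu
    spacing <- image$spacing
  }
  if (is.null(target)) target <- list(N = dim(vals), spacing = spacing)
  grid <- as.matrix(expand.grid(lapply(target$N, seq_len)))
  y <- spel_position(grid, rep_len(target$spacing, length(target$N)))
  src <- transform_points(field, y)
  vnum <- vals
  storage.mode(vnum) <- "double"
  out <- interp_at(vnum, spacing, src, method = interpolation, fill = fill)
  if (is.logical(vals)) out <- out > 0.5
  array(out, dim = target$N)
}

#' Map landmarks through a transformation
#'
#' Applies [transform_points()] to a landmark table in the field's source
#' space, e.g. to carry floating-space landmarks into reference space for
#' scoring against ground truth.
#'
#' @param points landmark matrix (rows; physical coordinates).
#' @param field a [bspline_field].
#' @return transformed landmark matrix.
#' @export
transform_landmarks <- function(points, field) {
  transform_points(field, points)
}

#' Coarse exhaustive rigid pre-alignment (2D)
#'
#' Plain grid search over rotation angles and a translation grid at
#' downsampled resolution, scoring each candidate pose by the directed
#' alpha-cut distance of the transformed floating spels into the reference.
#' Candidates whose mask overlap falls below `min_overlap` are rejected.
#' Intended as a cheap initializer before deformable registration when the
#' initial misalignment is large.
#'
#' @param ref,flo [fuzzy_image]s (2D).
#' @param angles rotation angles (radians) to try.
#' @param translations per-axis offsets (physical units) to try;
#'   defaults to a 9-point grid spanning a quarter of the extent.
#' @param min_overlap minimal fraction of floating mask spels landing
#'   inside the reference mask.
#' @param downsample resolution reduction factor for scoring.
#' @param n_alpha alpha samples for the scoring distance.
#' @return list with `angle`, `translation`, `score` and `transform`
#'   (a function mapping floating-space points to reference space).
#' @export
rigid_prealign <- function(ref, flo, angles = seq(-10, 10, length.out = 9) *
                             pi / 180,
                           translations = NULL, min_overlap = 0.4,
                           downsample = 4, n_alpha = 3) {
  stopifnot(length(ref$N) == 2, length(flo$N) == 2)
  sched <- stage_schedule(data.frame(
    subsampling_factor = downsample, sigma = 0, control_points = 4,
    iterations = 0, sampling_fraction = 1, d_max_per_diameter = 0.5,
    step_size = 1, momentum = 0, gw_m = 0, gw_sigma = 1), beta = 1, d_t = 0)
  refd <- build_pyramid(ref, sched)[[1]]
  flod <- build_pyramid(flo, sched)[[1]]
  trees <- alpha_trees(refd)
  ext <- image_extent(flod)$extent
  if (is.null(translations))
    translations <- lapply(ext, function(e) seq(-e / 4, e / 4,
                                                length.out = 9))
  d_max <- 0.5 * image_extent(refd)$diameter
  grid <- as.matrix(expand.grid(lapply(flod$N, seq_len)))
  pos <- spel_position(grid, flod$spacing)
  hts <- as.numeric(flod$mu)
  center <- ext / 2
  mask_pts <- if (!is.null(flod$mask)) as.numeric(flod$mask) > 0 else
    rep(TRUE, nrow(pos))
  alphas <- kronecker_alphas(n_alpha, offset = 0.5)
  best <- NULL
  for (th in angles) {
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rot <- sweep(sweep(pos, 2, center, "-") %*% t(Rm), 2, center, "+")
    for (tx in translations[[1]]) for (ty in translations[[2]]) {
      y <- sweep(rot, 2, c(tx, ty), "+")
      inm <- in_mask(y, refd)
      if (mean(inm[mask_pts]) < min_overlap) next
      mc <- mc_point_distances(y, hts, trees, alphas, d_max)
      keep <- mc$indomain & inm
      if (!any(keep)) next
      score <- mean(mc$value[keep])
      if (is.null(best) || score < best$score)
        best <- list(angle = th, translation = c(tx, ty), score = score)
    }
  }
  if (is.null(best))
    stop("no admissible pose: all candidates fall below the mask-overlap floor")
  best$transform <- function(points) {
    Rm <- matrix(c(cos(best$angle), sin(best$angle),
                   -sin(best$angle), cos(best$angle)), 2, 2)
    sweep(sweep(matrix(points, ncol = 2), 2, center, "-") %*% t(Rm),
          2, center + best$translation, "+")
  }
  best
}
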