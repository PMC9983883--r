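#' Random B-spline warp
#'
#' A [bspline_field] whose control displacements are independent uniform
#' draws from `(-range, range)` in every component, optionally rescaled so
#' the maximal displacement magnitude over a dense grid equals `max_disp`.
#' Used to build ground-truth deformations with known correspondence.
#'
#' @param extent physical extent of the support, per dimension.
#' @param counts control points per dimension.
#' @param range half-width of the uniform perturbation (physical units).
#' @param max_disp optional exact maximal displacement magnitude to scale
#'   to (scaling the mesh scales the displacement linearly).
#' @return a [bspline_field].
#' @export
random_bspline_warp <- function(extent, counts, range, max_disp = NULL) {
  n <- length(extent)
  counts <- rep_len(as.integer(counts), n)
  phi <- matrix(runif(prod(counts) * n, -range, range), prod(counts), n)
  f <- bspline_field(counts, extent, phi = phi)
  if (!is.null(max_disp)) {
    grids <- lapply(extent, function(e) seq(0, e, length.out = 65))
    disp <- field_displacement(f, as.matrix(expand.grid(grids)))
    mx <- max(sqrt(rowSums(disp^2)))
    if (mx > 0) f$phi <- f$phi * (max_disp / mx)
  }
  f
}

#' Stack of composed warps, coarse first
#'
#' Represents a coarse-to-fine sequence of random deformations.  Applying
#' the stack evaluates the finest field first and the coarsest last,
#' matching an image that was deformed by the coarse warp first and by each
#' finer warp afterwards (pull-back composition).
#'
#' @param fields list of [bspline_field]s ordered coarse to fine.
#' @return object of class `warp_stack`.
#' @export
warp_stack <- function(fields) {
  stopifnot(all(vapply(fields, inherits, TRUE, "bspline_field")))
  structure(list(fields = fields), class = "warp_stack")
}

#' @export
transform_points.warp_stack <- function(field, points) {
  for (f in rev(field$fields)) points <- transform_points(f, points)
  points
}

#' Deform a reference image with a known ground-truth warp
#'
#' Builds a floating/reference pair by pull-back resampling of the
#' reference through the warp (the warp maps floating coordinates into
#' reference space, the same convention as the recovered `T_AB`), deforming
#' the mask with nearest-neighbor interpolation, and laying down a regular
#' landmark grid with known correspondence.
#'
#' @param reference numeric array of reference intensities in \[0, 1\].
#' @param mask logical array, same shape.
#' @param warp a [bspline_field] or [warp_stack].
#' @param landmark_step grid step (spels) of the landmark lattice.
#' @return list of class `deformed_pair` with `reference`, `floating`,
#'   `ref_mask`, `flo_mask`, `warp`, and landmark matrices
#'   `landmarks_flo` / `landmarks_ref`.
#' @export
make_deformed_pair <- function(reference, mask, warp, landmark_step = 16) {
  stopifnot(identical(dim(reference), dim(mask)))
  N <- dim(reference)
  floating <- warp_image(fuzzy_image(reference), warp)
  flo_mask <- warp_image(array(as.numeric(mask), N), warp,
                         interpolation = "nearest") > 0.5
  grids <- lapply(N, function(m) seq(landmark_step, m - landmark_step,
                                     by = landmark_step) - 1)
  lm <- as.matrix(expand.grid(grids))
  dimnames(lm) <- NULL
  structure(list(reference = reference, floating = floating,
                 ref_mask = mask, flo_mask = flo_mask, warp = warp,
                 landmarks_flo = lm,
                 landmarks_ref = transform_points(warp, lm)),
            class = "deformed_pair")
}

#' Synthetic vessel phantom
#'
#' A reproducible 2D phantom emulating thin-structure statistics of retinal
#' vessel images: random branching tubes of width 1-6 spels with a smooth
#' intensity falloff, over a textured background.  The mask marks the tube
#' support.  Draws from the session RNG; set a seed for reproducibility.
#'
#' @param size image side length (`>= 64`).
#' @param target_fraction stop adding vessels when the mask reaches this
#'   area fraction.
#' @param max_walks cap on the number of vessel trees.
#' @return list with `image` (memberships in \[0, 1\]) and `mask`.
#' @export
make_vessel_phantom <- function(size = 128, target_fraction = 0.08,
                                max_walks = 40) {
  stopifnot(size >= 64)
  N <- c(size, size)
  bg <- matrix(rnorm(size^2), size, size)
  bg <- array(cpp_gauss_filter(as.numeric(bg), as.integer(N), 4, -1L), N)
  bg <- 0.12 + 0.03 * bg / stats::sd(bg)
  vess <- matrix(0, size, size)
  mask <- matrix(FALSE, size, size)

  stamp <- function(p, w, amp) {
    r <- ceiling(w / 2) + 1
    xs <- max(1, floor(p[1]) - r):min(size, ceiling(p[1]) + r)
    ys <- max(1, floor(p[2]) - r):min(size, ceiling(p[2]) + r)
    if (!length(xs) || !length(ys)) return()
    d2 <- outer((xs - 1 - p[1])^2, (ys - 1 - p[2])^2, "+")
    prof <- amp * exp(-1.2 * d2 / (w / 2)^2)
    vess[xs, ys] <<- pmax(vess[xs, ys], prof)
    mask[xs, ys] <<- mask[xs, ys] | (d2 <= (w / 2)^2)
  }

  walks <- 0
  queue <- list()
  while (mean(mask) < target_fraction && walks < max_walks) {
    walks <- walks + 1
    queue[[length(queue) + 1]] <- list(
      p = runif(2, 0.1, 0.9) * size, ang = runif(1, 0, 2 * pi),
      w = runif(1, 3, 6), amp = runif(1, 0.5, 1))
    while (length(queue) > 0) {
      br <- queue[[1]]
      queue[[1]] <- NULL
      p <- br$p; ang <- br$ang; w <- br$w; amp <- br$amp
      for (step in seq_len(400)) {
        stamp(p, w, amp)
        ang <- ang + rnorm(1, 0, 0.2)
        p <- p + 1.2 * c(cos(ang), sin(ang))
        w <- max(1, w * 0.997)
        if (any(p < 2) || any(p > size - 3) || w <= 1) break
        if (runif(1) < 0.02 && w > 2)
          queue[[length(queue) + 1]] <- list(
            p = p, ang = ang + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1),
            w = w * 0.75, amp = amp * 0.9)
      }
      if (mean(mask) >= target_fraction) break
    }
  }
  list(image = pmin(pmax(bg + vess, 0), 1), mask = mask)
}

#' Synthetically deformed retinal-style pair
#'
#' Reproduces the construction of a synthetic registration benchmark from a
#' fundus photograph with an annotated vessel mask: grayscale conversion by
#' channel averaging, rolling-ball background removal (grayscale
#' ball-opening, subtracted) to strip low-frequency features, padding, and
#' a coarse-to-fine sequence of random B-spline deformations composed
#' coarse-first (mesh counts 7, 14, 24, 48 per dimension with uniform
#' per-parameter perturbations of 250, 50, 25 and 15 px at full scale).
#' The `scale` argument shrinks the perturbations and padding
#' proportionally for reduced-resolution inputs.
#'
#' @param image grayscale matrix or RGB array (third dimension = channels).
#' @param mask logical vessel mask matching the image plane.
#' @param counts control counts of the deformation levels.
#' @param perturb uniform perturbation half-widths per level (px, full
#'   scale).
#' @param pad padding (px, full scale) added on each side.
#' @param ball_radius rolling-ball radius (px).
#' @param scale resolution scale of the input relative to full-size fundus
#'   images; perturbations and padding are multiplied by it.
#' @param landmark_step landmark lattice step (spels).
#' @return a `deformed_pair`, see [make_deformed_pair()].
#' @export
make_retinal_pair <- function(image, mask, counts = c(7, 14, 24, 48),
                              perturb = c(250, 50, 25, 15), pad = 350,
                              ball_radius = 20, scale = 1,
                              landmark_step = 16) {
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), mean)
  if (!identical(dim(image), dim(mask)))
    stop("mask shape must match the image plane")
  img <- image / max(image, 1e-12)
  # background flattening: subtract the grayscale ball-opening
  er <- cpp_grey_ball_morph(img, ball_radius, TRUE)
  bgd <- cpp_grey_ball_morph(er, ball_radius, FALSE)
  img <- pmin(pmax(img - bgd, 0), 1)
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  padn <- round(pad * scale)
  N0 <- dim(img)
  N <- N0 + 2 * padn
  padded <- matrix(0, N[1], N[2])
  padded[padn + seq_len(N0[1]), padn + seq_len(N0[2])] <- img
  pmask <- matrix(FALSE, N[1], N[2])
  pmask[padn + seq_len(N0[1]), padn + seq_len(N0[2])] <- mask
  ext <- N - 1
  fields <- mapply(function(cc, pr) {
    random_bspline_warp(ext, cc, pr * scale)
  }, counts, perturb, SIMPLIFY = FALSE)
  make_deformed_pair(padded, pmask, warp_stack(fields),
                     landmark_step = landmark_step)
}

#' Jaccard index of two masks
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both masks are empty
#' (with a message).
#'
#' @param a,b logical arrays of equal shape.
#' @export
jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  uni <- sum(a | b)
  if (uni == 0) {
    message("jaccard: both masks empty; returning 1")
    return(1)
  }
  sum(a & b) / uni
}

#' Mean Euclidean landmark error
#'
#' @param pred,gt matched landmark matrices (equal row counts and order).
#' @export
mean_landmark_error <- function(pred, gt) {
  pred <- as.matrix(pred)
  gt <- as.matrix(gt)
  stopifnot(identical(dim(pred), dim(gt)))
  mean(sqrt(rowSums((pred - gt)^2)))
}

#' Target overlap of warped labels against reference labels
#'
#' Per reference label `l`: the fraction of its spels covered by the same
#' label after warping, `|warped == l & ref == l| / |ref == l|`, measured
#' in reference space; the background label 0 is excluded.
#'
#' @param warped,ref integer label arrays of equal shape.
#' @return list with `per_label` (named vector) and `mean`.
#' @export
target_overlap <- function(warped, ref) {
  stopifnot(identical(dim(warped), dim(ref)))
  labs <- sort(setdiff(unique(as.vector(ref)), 0))
  per <- vapply(labs, function(l) {
    sum(warped == l & ref == l) / sum(ref == l)
  }, numeric(1))
  names(per) <- labs
  list(per_label = per, mean = mean(per))
}

#' Success-rate curve over error thresholds
#'
#' For each threshold, the fraction of registrations whose error does not
#' exceed it; non-decreasing in the threshold.
#'
#' @param errors numeric vector of per-case errors.
#' @param thresholds numeric thresholds.
#' @export
success_rate_curve <- function(errors, thresholds) {
  vapply(thresholds, function(t) mean(errors <= t), numeric(1))
}
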