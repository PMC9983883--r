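#' Cubic B-spline free-form deformation field
#'
#' A displacement field spanned by a `c_1 x ... x c_n` mesh of control-point
#' displacement vectors with uniform spacing `delta` per dimension.  The
#' transformation is `T(x) = x + sum of tensor-product cubic B-spline basis
#' weights times the 4^n supporting control displacements`; outside the
#' finite support it is the identity.
#'
#' The default mesh placement covers a physical extent `E` (typically the
#' image extent from [image_extent()]): `delta = E / (counts - 3)` with the
#' mesh origin one spacing below the image origin, so every in-image point
#' has a full 4-neighborhood of controls and the support equals the image
#' box.  Fields live in physical coordinates, so a field estimated on a
#' coarse pyramid level applies unchanged at finer levels.
#'
#' @param counts control points per dimension, each `>= 4`.
#' @param extent physical extent covered by the support, per dimension.
#' @param phi optional `prod(counts) x n` matrix of control displacements
#'   (column-major mesh flattening); defaults to the zero (identity) field.
#' @param origin physical position of control index 0; defaults to
#'   `-delta`.
#' @return An object of class `bspline_field`.
#' @examples
#' f <- bspline_field(c(6, 6), extent = c(31, 31))
#' transform_points(f, rbind(c(10, 12)))  # identity: zero mesh
#' @export
bspline_field <- function(counts, extent, phi = NULL, origin = NULL) {
  counts <- as.integer(counts)
  n <- length(counts)
  if (any(counts < 4)) stop("need at least 4 control points per dimension")
  extent <- rep_len(as.numeric(extent), n)
  delta <- extent / (counts - 3)
  if (any(delta <= 0)) stop("extent must be strictly positive")
  if (is.null(origin)) origin <- -delta
  if (is.null(phi)) phi <- matrix(0, prod(counts), n)
  phi <- matrix(as.numeric(phi), prod(counts), n)
  structure(list(phi = phi, counts = counts, delta = delta,
                 origin = rep_len(as.numeric(origin), n), extent = extent),
            class = "bspline_field")
}

#' @export
print.bspline_field <- function(x, ...) {
  cat("<bspline_field> mesh ", paste(x$counts, collapse = " x "),
      ", spacing (", paste(format(x$delta, digits = 4), collapse = ", "),
      "), max |disp| ", format(max(sqrt(rowSums(x$phi^2))), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Cubic B-spline basis weights
#'
#' The four cubic basis functions evaluated at a fractional offset:
#' `B0 = (1-u)^3/6`, `B1 = (3u^3 - 6u^2 + 4)/6`,
#' `B2 = (-3u^3 + 3u^2 + 3u + 1)/6`, `B3 = u^3/6`.  Non-negative and summing
#' to one (partition of unity).
#'
#' @param u fractional offset in \[0, 1).
#' @return numeric vector of the 4 weights.
#' @export
basis_weights <- function(u) {
  stopifnot(u >= 0, u < 1)
  cpp_basis_weights(u)
}

#' Apply a B-spline transformation to points
#'
#' @param field a [bspline_field] (or a [warp_stack] of composed fields).
#' @param points matrix of physical points (rows), or a single point.
#' @return matrix of transformed points.
#' @export
transform_points <- function(field, points) UseMethod("transform_points")

#' @export
transform_points.bspline_field <- function(field, points) {
  points <- matrix(as.numeric(points), ncol = length(field$counts))
  points + cpp_bspline_disp(points, field$phi, field$counts, field$delta,
                            field$origin)
}

# displacement only (same layout as transform_points)
field_displacement <- function(field, points) {
  points <- matrix(as.numeric(points), ncol = length(field$counts))
  cpp_bspline_disp(points, field$phi, field$counts, field$delta,
                   field$origin)
}

#' Sparse parameter Jacobian of a B-spline transformation
#'
#' `dT(x)/dPhi_i` is the tensor-product basis weight of control `i` at `x`
#' (identical across vector components); at most `4^n` are nonzero per
#' point, and they sum to 1 for points interior to the support.
#'
#' @inheritParams transform_points
#' @return list with `idx` (`npts x 4^n` 1-based control indices, 0 outside
#'   the support), `w` (matching weights) and `inside` (logical per point).
#' @export
param_jacobian <- function(field, points) {
  points <- matrix(as.numeric(points), ncol = length(field$counts))
  cpp_bspline_weights(points, field$counts, field$delta, field$origin)
}

#' Compose two B-spline transformations at points
#'
#' Evaluates `outer(inner(x))` without resampling either field.
#'
#' @param outer,inner [bspline_field]s.
#' @inheritParams transform_points
#' @export
compose_points <- function(outer, inner, points) {
  transform_points(outer, transform_points(inner, points))
}

# spatial Jacobian dT/dx of a field at points, analytic (derivative basis
# functions); J[p, a, k] = dT_a/dx_k, identity outside the support
field_spatial_jacobian <- function(field, points) {
  points <- matrix(as.numeric(points), ncol = length(field$counts))
  n <- ncol(points)
  J <- array(cpp_bspline_jacobian(points, field$phi, field$counts,
                                  field$delta, field$origin),
             c(nrow(points), n, n))
  for (k in seq_len(n)) J[, k, k] <- J[, k, k] + 1
  J
}

#' Refine a B-spline field to a denser control mesh
#'
#' Fits a field on the finer mesh to the displacement of the input field by
#' linear least squares on a dense sample grid (`samples_per_span` per new
#' knot span per dimension).  Used between stages of the coarse-to-fine
#' schedule; for nested meshes (spacing halved, `c' = 2c - 3`) the fit is
#' exact to numerical precision, for the non-dyadic count progressions of
#' the shipped schedules it is a close approximation.
#'
#' @param field a [bspline_field].
#' @param counts new per-dimension control counts, each `>= ` the old count.
#' @param samples_per_span dense-grid density; at least 4 to keep the fit
#'   over-determined.
#' @return the refined [bspline_field].
#' @export
refine <- function(field, counts, samples_per_span = 4) {
  counts <- as.integer(counts)
  n <- length(field$counts)
  stopifnot(length(counts) == n, all(counts >= field$counts))
  if (samples_per_span < 4)
    stop("need at least 4 samples per knot span for a determined fit")
  newf <- bspline_field(counts, field$extent)
  grids <- lapply(seq_len(n), function(k) {
    m <- (counts[k] - 3) * samples_per_span + 1
    seq(0, field$extent[k], length.out = m)
  })
  pts <- as.matrix(expand.grid(grids))
  disp <- field_displacement(field, pts)
  jac <- param_jacobian(newf, pts)
  keep <- which(jac$inside)
  A <- Matrix::sparseMatrix(
    i = rep(keep, ncol(jac$idx)),
    j = as.vector(jac$idx[keep, ]),
    x = as.vector(jac$w[keep, ]),
    dims = c(nrow(pts), prod(counts)))
  AtA <- Matrix::crossprod(A)
  phi <- as.matrix(Matrix::solve(AtA, Matrix::crossprod(A, disp[keep, ,
                                                                drop = FALSE])))
  bspline_field(counts, field$extent, phi = phi)
}
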