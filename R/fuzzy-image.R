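#' Spatial fuzzy set representation of a grayscale image
#'
#' Wraps a membership grid (intensities in \[0, 1\]) together with its spel
#' spacing and optional mask and weight grids of the same shape.  Spel
#' centers sit at physical position `index * spacing` with 0-based indices,
#' so the grid occupies the physical box `[0, (N - 1) * spacing]`.
#'
#' @param values numeric matrix (2D) or 3D array with all values in \[0, 1\].
#' @param spacing positive spel spacing, recycled per dimension.
#' @param mask optional logical array of the same shape; `TRUE` spels take
#'   part in matching.
#' @param weights optional non-negative array of the same shape, used to
#'   weight sampled points in the objective.
#' @return An object of class `fuzzy_image`.
#' @examples
#' img <- fuzzy_image(matrix(runif(64), 8, 8))
#' dim(img$mu)
#' @export
fuzzy_image <- function(values, spacing = 1, mask = NULL, weights = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = length(values))
  n <- length(dim(values))
  if (n < 2 || n > 3) stop("only 2D and 3D images are supported")
  rng <- range(values, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("memberships must lie in [0, 1]; run preprocess_image() first")
  spacing <- rep_len(as.numeric(spacing), n)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(values)))
      stop("mask shape must match the membership grid")
    storage.mode(mask) <- "logical"
  }
  if (!is.null(weights)) {
    if (!identical(dim(weights), dim(values)))
      stop("weights shape must match the membership grid")
    if (any(weights < 0)) stop("weights must be non-negative")
  }
  structure(
    list(mu = values, spacing = spacing, N = dim(values),
         mask = mask, weights = weights),
    class = "fuzzy_image")
}

#' @export
print.fuzzy_image <- function(x, ...) {
  cat("<fuzzy_image> ", paste(x$N, collapse = " x "),
      " spels, spacing (", paste(format(x$spacing), collapse = ", "), ")",
      if (!is.null(x$mask)) ", masked" else "",
      if (!is.null(x$weights)) ", weighted" else "", "\n", sep = "")
  invisible(x)
}

#' Physical extent and diagonal of an image grid
#'
#' The extent spans the spel centers, `(N - 1) * spacing` per dimension; the
#' diameter is the Euclidean norm of the extent and is the reference length
#' for the `d_max` truncation fractions of a stage schedule.
#'
#' @param image a [fuzzy_image].
#' @return list with `extent` and `diameter`.
#' @export
image_extent <- function(image) {
  ext <- (image$N - 1) * image$spacing
  list(extent = ext, diameter = sqrt(sum(ext^2)))
}

# physical coordinates of spel centers for 1-based array indices
spel_position <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, "*")
}

# 1-based array indices of the nearest spel for physical points; NA outside
nearest_spel <- function(pts, image) {
  idx <- round(sweep(pts, 2, image$spacing, "/")) + 1
  bad <- idx < 1 | sweep(idx, 2, image$N, ">")
  idx[rowSums(bad) > 0, ] <- NA_integer_
  idx
}

# logical: point is inside the mask (TRUE where mask is NULL but in-grid)
in_mask <- function(pts, image) {
  idx <- nearest_spel(pts, image)
  ok <- !is.na(idx[, 1])
  if (!is.null(image$mask)) {
    flat <- rep(FALSE, nrow(pts))
    if (any(ok)) {
      lin <- linear_index(idx[ok, , drop = FALSE], image$N)
      flat[ok] <- image$mask[lin]
    }
    flat
  } else ok
}

# column-major linear index from 1-based array indices
linear_index <- function(idx, N) {
  lin <- idx[, 1]
  stride <- 1
  for (k in seq_along(N)[-1]) {
    stride <- stride * N[k - 1]
    lin <- lin + (idx[, k] - 1) * stride
  }
  lin
}
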