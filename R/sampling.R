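#' Generalized golden ratios for Kronecker sequences
#'
#' Returns the irrational step vector `a_j = phi_n^(-j)` where `phi_n` is the
#' fixed point of `x = (1 + x)^(1 / (n + 1))` (the golden ratio for `n = 1`,
#' the plastic number for `n = 2`), solved by fixed-point iteration to
#' `1e-14`.  These steps give low-discrepancy `n`-dimensional Kronecker
#' sequences.
#'
#' @param n dimension, `>= 1`.
#' @return numeric vector `a_1..a_n`, each in (0, 1).
#' @export
golden_ratios <- function(n) {
  stopifnot(n >= 1)
  phi <- 2
  repeat {
    nxt <- (1 + phi)^(1 / (n + 1))
    if (abs(nxt - phi) < 1e-15) break
    phi <- nxt
  }
  phi^-(seq_len(n))
}

#' Quasi-random integer grid points from a Kronecker sequence
#'
#' The `i`-th sample has coordinates `floor((i * a_j mod 1) * N_j)` with the
#' generalized golden-ratio steps of [golden_ratios()].  Deterministic given
#' the start index; a random start index turns the stream into an unbiased
#' (but stratified) uniform sampler.
#'
#' @param count number of points.
#' @param N domain size per dimension.
#' @param start index of the first sample (0 gives the origin).
#' @return `count x n` matrix of 0-based integer grid coordinates.
#' @export
kronecker_points <- function(count, N, start = 0) {
  stopifnot(count >= 1)
  n <- length(N)
  a <- golden_ratios(n)
  i <- start + seq_len(count) - 1
  pts <- matrix(0L, count, n)
  for (j in seq_len(n)) {
    frac <- (i * a[j]) %% 1
    pts[, j] <- pmin(floor(frac * N[j]), N[j] - 1)
  }
  pts
}

#' Sampler configuration for the mixture point sampler
#'
#' @param m mixture weight in \[0, 1\]: probability of drawing from the
#'   gradient-weighted sampler rather than the quasi-uniform stream.
#' @param sigma_gm scale (in spels) of the Gaussian derivative used for the
#'   gradient-magnitude map.
#' @param t_gm gradient-magnitude threshold; values below it carry no
#'   sampling mass (default 0).
#' @param fraction fraction of domain spels drawn per iteration.
#' @param quasi use the Kronecker stream for the uniform component (plain
#'   RNG-uniform available for ablation).
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(m = 0.5, sigma_gm = 1, t_gm = 0, fraction = 0.05,
                           quasi = TRUE) {
  stopifnot(m >= 0, m <= 1, sigma_gm > 0, t_gm >= 0,
            fraction > 0, fraction <= 1)
  structure(list(m = m, sigma_gm = sigma_gm, t_gm = t_gm,
                 fraction = fraction, quasi = quasi),
            class = "sampler_config")
}

#' Gradient-weighted sampling probability map
#'
#' Normalized spatial Gaussian gradient magnitude of the membership grid:
#' the Euclidean norm of the per-axis Gaussian first derivatives at scale
#' `sigma_gm` (reflected boundaries), thresholded at `t_gm` and normalized
#' to sum 1.  Degenerate (all mass removed, e.g. a constant image) maps are
#' flagged and the caller falls back to uniform sampling.  The map depends
#' only on the image, not on the current transformation, so it is computed
#' once per pyramid level.
#'
#' @param image a [fuzzy_image].
#' @param sigma_gm,t_gm see [sampler_config()].
#' @return the probability array, or `NULL` when degenerate.
#' @export
gradient_weight_map <- function(image, sigma_gm, t_gm = 0) {
  stopifnot(sigma_gm > 0)
  n <- length(image$N)
  gm2 <- 0
  for (k in seq_len(n)) {
    g <- cpp_gauss_filter(as.numeric(image$mu), as.integer(image$N),
                          sigma_gm, k) / image$spacing[k]
    gm2 <- gm2 + g^2
  }
  gm <- sqrt(gm2)
  # numerical floor: a constant image leaves round-off residue, not signal
  gm[gm < max(t_gm, 1e-10)] <- 0
  total <- sum(gm)
  if (total <= 0) return(NULL)
  array(gm / total, dim = image$N)
}

#' Draw sample points from the mixture sampler
#'
#' Per draw, a sampler is first selected at random — the gradient-weighted
#' map with probability `m`, the (quasi-)uniform stream otherwise — and a
#' point is then drawn from it, with replacement.  The quasi-uniform stream
#' is a Kronecker sequence with a random start index per call; a degenerate
#' gradient map falls back to uniform draws.
#'
#' @param image a [fuzzy_image].
#' @param count number of points.
#' @param config a [sampler_config].
#' @param map optional precomputed [gradient_weight_map()] (cached per
#'   pyramid level by [run_stage()]); computed on the fly when missing and
#'   `m > 0`.
#' @return list with `idx` (1-based array indices), `pos` (physical
#'   coordinates), `height` (memberships), and `weight` (the image weight
#'   grid at the points, 1 where absent).
#' @export
draw_points <- function(image, count, config, map = NULL) {
  stopifnot(count >= 1)
  n <- length(image$N)
  npx <- prod(image$N)
  if (is.null(map) && config$m > 0)
    map <- gradient_weight_map(image, config$sigma_gm, config$t_gm)
  use_gw <- if (config$m > 0 && !is.null(map))
    runif(count) < config$m else rep(FALSE, count)
  lin <- integer(count)
  ngw <- sum(use_gw)
  if (ngw > 0) {
    cdf <- cumsum(as.numeric(map))
    lin[use_gw] <- findInterval(runif(ngw) * cdf[npx], cdf) + 1L
  }
  nun <- count - ngw
  if (nun > 0) {
    if (config$quasi) {
      start <- sample.int(.Machine$integer.max, 1)
      pts0 <- kronecker_points(nun, image$N, start = start)
      lin[!use_gw] <- linear_index(pts0 + 1, image$N)
    } else {
      lin[!use_gw] <- sample.int(npx, nun, replace = TRUE)
    }
  }
  idx <- arrayInd(lin, image$N)
  pos <- spel_position(idx, image$spacing)
  w <- if (is.null(image$weights)) rep(1, count) else image$weights[lin]
  list(idx = idx, pos = pos, height = as.numeric(image$mu)[lin], weight = w)
}
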