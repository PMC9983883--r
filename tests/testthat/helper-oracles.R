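# Independent brute-force oracles used across the suite.  These never touch
# the KD-tree or the C++ estimator: distances come from exhaustive linear
# scans over spel centers.

rand_image <- function(n = 8, spacing = 1) {
  fuzzy_image(array(runif(prod(rep(n, 2))), rep(n, 2)), spacing = spacing)
}

grid_positions <- function(image) {
  idx <- as.matrix(expand.grid(lapply(image$N, seq_len)))
  sweep(idx - 1, 2, image$spacing, "*")
}

# exact distance from one point to the alpha-cut of an image (linear scan),
# truncated at d_max; empty cut -> d_max
brute_cut_distance <- function(p, image, alpha, d_max = Inf,
                               complement = FALSE) {
  mu <- as.numeric(image$mu)
  if (complement) mu <- 1 - mu
  sel <- mu >= alpha
  if (!any(sel)) return(d_max)
  pos <- grid_positions(image)
  min(min(sqrt(rowSums(sweep(pos[sel, , drop = FALSE], 2, p, "-")^2))),
      d_max)
}

# the per-level estimator d'(p, S; alpha) by linear scan (object branch for
# alpha <= h, complement branch otherwise)
brute_dprime <- function(p, h, image, alpha, d_max) {
  if (alpha <= h) brute_cut_distance(p, image, alpha, d_max)
  else brute_cut_distance(p, image, 1 - alpha, d_max, complement = TRUE)
}

# enumerate every (node index, rectangle) of the KD-tree by replaying the
# split recursion in R
enumerate_tree_rects <- function(N, spacing) {
  out <- list()
  rec <- function(i, y, R) {
    out[[length(out) + 1]] <<- list(i = i, y = y, R = R)
    if (prod(R) == 1) return()
    s <- split_rect(y, R, spacing)
    rec(2 * i, s$left$y, s$left$R)
    rec(2 * i + 1, s$right$y, s$right$R)
  }
  rec(1, rep(0L, length(N)), as.integer(N))
  out
}

# uniform-stream sample set over all spels of an image (deterministic)
all_points <- function(image) {
  idx <- as.matrix(expand.grid(lapply(image$N, seq_len)))
  list(idx = idx, pos = sweep(idx - 1, 2, image$spacing, "*"),
       height = as.numeric(image$mu), weight = rep(1, prod(image$N)))
}

# exhaustive alpha levels for a (pair of) images: midpoints between the
# distinct membership values, covering both object and complement branches
exhaustive_alphas <- function(...) {
  mu <- sort(unique(unlist(lapply(list(...), function(im)
    c(as.numeric(im$mu), 1 - as.numeric(im$mu))))))
  mids <- (head(mu, -1) + tail(mu, -1)) / 2
  mids[mids > 0 & mids < 1]
}
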