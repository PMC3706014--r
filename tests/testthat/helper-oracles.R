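# Independent oracles used to derive expected values and to cross-check the
# compiled scan against the plain-R formulation.

# point-to-infinite-line distance in the slope/intercept form
# |k*x - y + b| / sqrt(k^2 + 1); only defined for non-vertical lines
pt_line_dist_kb <- function(px, py, ax, ay, bx, by) {
  k <- (ay - by) / (ax - bx)
  b <- ay - k * ax
  abs(k * px - py + b) / sqrt(k^2 + 1)
}

# reference greedy built on the exported R-level criterion (independent of
# the compiled window scan)
ref_greedy <- function(points, w = distance_weights()) {
  p <- presee:::as_points(points)
  n <- length(p$x)
  cps <- 1L
  start <- 1L
  cur <- start + 2L
  while (cur <= n) {
    if (prefer_segment(points, start, cur, w)) {
      cur <- cur + 1L
    } else {
      cps <- c(cps, cur - 1L)
      start <- cur - 1L
      cur <- start + 2L
    }
  }
  c(cps, n)
}

# total code length of a segmentation given its character-point positions
total_cost <- function(points, cps, w = distance_weights()) {
  sum(vapply(seq_len(length(cps) - 1),
             function(s) mdl_seg(points, cps[s], cps[s + 1], w),
             numeric(1)))
}

# exact global optimum of the total code length over all character-point
# subsets containing both endpoints: shortest path on the segment DAG
dag_opt_cost <- function(points, w = distance_weights()) {
  p <- presee:::as_points(points)
  n <- length(p$x)
  best <- rep(Inf, n)
  best[1] <- 0
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      c_ij <- mdl_seg(points, i, j, w)
      if (best[i] + c_ij < best[j]) best[j] <- best[i] + c_ij
    }
  }
  best[n]
}

# brute-force enumeration over interior-point subsets (small n only)
enum_opt_cost <- function(points, w = distance_weights()) {
  p <- presee:::as_points(points)
  n <- length(p$x)
  interior <- if (n > 2) 2:(n - 1) else integer(0)
  best <- Inf
  for (mask in 0:(2^length(interior) - 1)) {
    keep <- interior[bitwAnd(mask, 2^(seq_along(interior) - 1)) > 0]
    best <- min(best, total_cost(points, c(1L, keep, n), w))
  }
  best
}

# rigid motion of a point set / segment coordinates
rotate_pts <- function(x, y, theta, dx = 0, dy = 0) {
  list(x = cos(theta) * x - sin(theta) * y + dx,
       y = sin(theta) * x + cos(theta) * y + dy)
}

rand_segment <- function() {
  v <- stats::runif(4, -10, 10)
  segment(min(v[1], v[3]), v[2], max(v[1], v[3]) + 0.5, v[4])
}

# small rough random walk in (index, value), unit index spacing
rand_walk <- function(n, scale = 5) {
  data.frame(index = 0:(n - 1), value = cumsum(stats::runif(n, -scale, scale)))
}

make_source <- function(points) presee:::points_source(points)
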