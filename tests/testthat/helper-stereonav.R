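# shared fixtures, built in code

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# dense, deliberately asymmetric surface (a bent sheet sampled at random
# points, as a pointer sweep would) for ICP tests; uses the caller's RNG state
bent_sheet_cloud <- function(n = 600, extent = 10) {
  x <- stats::runif(n, -extent, extent)
  y <- stats::runif(n, -extent, extent)
  cbind(x, y, 0.08 * x^2 - 0.05 * y^2 + 0.03 * x * y)
}

# brute-force point-to-line distance by dense grid search over t
grid_line_distance <- function(p, a, d, t_range = 50, n = 200001) {
  t <- seq(-t_range, t_range, length.out = n)
  pts <- outer(t, d)
  min(sqrt((p[1] - a[1] - pts[, 1])^2 +
             (p[2] - a[2] - pts[, 2])^2 +
             (p[3] - a[3] - pts[, 3])^2))
}
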