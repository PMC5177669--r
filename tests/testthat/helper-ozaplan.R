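# Shared fixtures, built once per test run (all generation is in code).

default_skull <- generate_skull()                       # 70 x 90 x 65 mm
small_skull <- generate_skull(skull_params(c(35, 45, 32), subdivisions = 3))

default_center <- c(0, 0, default_skull$params$center_height)

# Uniform points inside an ellipsoid (rejection-free: scaled ball sampling).
runif_in_ellipsoid <- function(n, semi_axes, center = c(0, 0, 0), shrink = 0.95) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- stats::runif(n)^(1 / 3) * shrink
  sweep(u * r, 2, semi_axes, `*`) + rep(center, each = n)
}

# Independent Pearson oracle: covariance formula + t-distribution p-value.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}
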