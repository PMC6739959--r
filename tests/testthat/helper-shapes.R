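# Shared helpers for the test suite.

# Rotate a k x 2 configuration by `theta` radians.
rot2 <- function(m, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  m %*% R
}

# Deterministic random k x 2 configuration.
randShape <- function(k, seed) {
  set.seed(seed)
  matrix(stats::rnorm(2 * k), k, 2)
}

# k x 2 x n array of jittered similarity copies of one base shape.
jitteredCopies <- function(base, n, seed, noise = 0.01) {
  set.seed(seed)
  k <- nrow(base)
  a <- array(0, dim = c(k, 2, n))
  for (i in seq_len(n)) {
    m <- base + matrix(stats::rnorm(2 * k, sd = noise), k, 2)
    m <- rot2(m, stats::runif(1, 0, 2 * pi)) * stats::runif(1, 0.5, 2)
    a[, , i] <- sweep(m, 2, stats::runif(2, -3, 3), "+")
  }
  a
}

# Full Procrustes distance of two centered pre-scaled shapes by brute-force
# search over rotation angles (grid in radians).
gridProcrustesDistance <- function(a, b, step = 1e-4) {
  pre <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- pre(a); b <- pre(b)
  thetas <- seq(0, 2 * pi, by = step)
  best <- Inf
  for (th in thetas) {
    d <- sqrt(sum((rot2(a, th) - b)^2))
    if (d < best) best <- d
  }
  best
}
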