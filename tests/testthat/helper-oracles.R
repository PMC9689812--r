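# Independent brute-force oracles and small generators shared across tests.

# O(R*S*k^2) window statistics with replicate padding, the definitional
# counterpart of the integral-image implementation.
brute_local_stats <- function(xi, k) {
  r <- (k - 1) / 2
  R <- nrow(xi); S <- ncol(xi)
  mu <- sg <- matrix(0, R, S)
  for (i in seq_len(R)) for (j in seq_len(S)) {
    ri <- pmin(pmax((i - r):(i + r), 1), R)
    ci <- pmin(pmax((j - r):(j + r), 1), S)
    w <- xi[ri, ci]
    mu[i, j] <- mean(w)
    sg[i, j] <- sqrt(mean((w - mean(w))^2))  # population sd
  }
  list(mean = mu, sd = sg, global_mean = mean(xi))
}

# Per-pixel evaluation of the printed 3x3 Sobel sums, border ring zero.
brute_sobel <- function(xi) {
  R <- nrow(xi); S <- ncol(xi)
  out <- matrix(0, R, S)
  for (i in 2:(R - 1)) for (j in 2:(S - 1)) {
    h <- xi[i + 1, j + 1] + 2 * xi[i + 1, j] + xi[i + 1, j - 1] -
      xi[i - 1, j - 1] - 2 * xi[i - 1, j] - xi[i - 1, j + 1]
    v <- xi[i + 1, j + 1] + 2 * xi[i, j + 1] + xi[i - 1, j + 1] -
      xi[i - 1, j - 1] - 2 * xi[i, j - 1] - xi[i + 1, j - 1]
    out[i, j] <- sqrt(h^2 + v^2)
  }
  out
}

random_rgb <- function(R = 12, S = 12) {
  array(runif(R * S * 3), dim = c(R, S, 3))
}

random_mask <- function(R = 10, S = 10, p = 0.5) {
  matrix(runif(R * S) < p, R, S)
}

# small fixture image reused by optimiser tests
tiny_fixture_xi <- function(seed = 1, rows = 16, cols = 16) {
  fx <- make_lesion_image(lesion_spec(rows = rows, cols = cols, seed = seed))
  rgb_to_hsi(fx$image)$intensity
}
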