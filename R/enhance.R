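#' Local mean and standard deviation maps
#'
#' Computes, for every pixel, the mean and population standard deviation of
#' the `k x k` window centred on it, using replicate padding at the image
#' border, plus the global mean. Implemented with integral images so the
#' cost is independent of `k`.
#'
#' @param xi numeric matrix, the intensity channel with values in `[0, 1]`.
#' @param k odd window size, `3 <= k <= min(dim(xi))`.
#' @return list with `mean` and `sd` matrices (same dimension as `xi`),
#'   the window size `k`, and `global_mean`.
#' @export
#' @examples
#' xi <- matrix(runif(64), 8, 8)
#' st <- local_stats(xi, k = 3)
#' str(st)
local_stats <- function(xi, k = 7) {
  stopifnot(is.matrix(xi), all(is.finite(xi)))
  if (length(k) != 1 || k %% 2 != 1 || k < 3 || k > min(dim(xi)))
    stop("k must be an odd integer with 3 <= k <= min(dim(xi))")
  r <- (k - 1) / 2
  R <- nrow(xi); S <- ncol(xi)
  ri <- pmin(pmax(seq(1 - r, R + r), 1), R)
  ci <- pmin(pmax(seq(1 - r, S + r), 1), S)
  pad <- xi[ri, ci, drop = FALSE]

  win_sum <- function(m) {
    s <- apply(rbind(0, m), 2, cumsum)
    s <- t(apply(cbind(0, s), 1, cumsum))
    # window rows i..i+k-1, cols j..j+k-1 of the padded image
    s[(1:R) + k, (1:S) + k] - s[1:R, (1:S) + k] -
      s[(1:R) + k, 1:S] + s[1:R, 1:S]
  }

  n <- k * k
  mu <- win_sum(pad) / n
  ex2 <- win_sum(pad^2) / n
  sigma <- sqrt(pmax(ex2 - mu^2, 0))
  list(mean = mu, sd = sigma, k = k, global_mean = mean(xi))
}

#' Brightness-preserving local contrast transform
#'
#' Applies the four-parameter enhancement
#' `g = delta * M / (sigma + beta + eps) * (f - gamma * mu) + mu^alpha`
#' to every pixel, where `f` is the original intensity, `mu`/`sigma` are the
#' local window mean and standard deviation, and `M` is the global mean.
#' The gain term stretches local contrast while the `mu^alpha` addend
#' re-injects (a power of) the local mean, limiting brightness drift. The
#' result is clipped to `[0, 1]`. All arithmetic is on the `[0, 1]` intensity
#' scale; `0^0` follows the limit convention `1`.
#'
#' @param xi intensity matrix in `[0, 1]`.
#' @param params numeric vector `(alpha, beta, gamma, delta)`. Bounds are not
#'   enforced here; the optimisers clip candidates before evaluation.
#' @param stats local statistics of `xi` from [local_stats()].
#' @param eps small additive guard in the gain denominator so that
#'   `sigma = beta = 0` (reachable: the lower bound of beta is 0) never
#'   divides by zero.
#' @return enhanced intensity matrix, same dimension, values in `[0, 1]`.
#' @export
enhance_intensity <- function(xi, params, stats, eps = 1e-6) {
  stopifnot(length(params) == 4, all(is.finite(params)))
  if (!all(dim(xi) == dim(stats$mean)))
    stop("stats were not computed from this channel (shape mismatch)")
  alpha <- params[[1]]; beta <- params[[2]]
  gamma <- params[[3]]; delta <- params[[4]]
  gain <- delta * stats$global_mean / (stats$sd + beta + eps)
  g <- gain * (xi - gamma * stats$mean) + stats$mean^alpha
  pmin(pmax(g, 0), 1)
}

#' Default decision-variable bounds
#'
#' The search box for the four transform parameters:
#' `lb = (0, 0, 0, 0.5)`, `ub = (1.6, 0.5, 0.8, 1.5)` for
#' `(alpha, beta, gamma, delta)`.
#'
#' @return list with named numeric vectors `lb` and `ub`.
#' @export
default_bounds <- function() {
  list(lb = c(alpha = 0,   beta = 0,   gamma = 0,   delta = 0.5),
       ub = c(alpha = 1.6, beta = 0.5, gamma = 0.8, delta = 1.5))
}

#' Clamp a parameter vector into the search box
#'
#' @param v numeric vector of length 4.
#' @param lb,ub componentwise bounds.
#' @return the componentwise `min(max(v, lb), ub)`.
#' @export
clip_bounds <- function(v, lb, ub) {
  pmin(pmax(v, lb), ub)
}
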