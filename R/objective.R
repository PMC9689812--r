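#' Sobel gradient magnitude map
#'
#' Evaluates the horizontal and vertical 3x3 Sobel sums at every interior
#' pixel and returns `sqrt(h^2 + v^2)`; the one-pixel border ring is set to
#' zero (no wraparound, no padding).
#'
#' @param xi intensity matrix, at least 3 x 3.
#' @return non-negative matrix of the same dimension.
#' @export
sobel_magnitude <- function(xi) {
  stopifnot(is.matrix(xi))
  R <- nrow(xi); S <- ncol(xi)
  if (R < 3 || S < 3) stop("image must be at least 3 x 3 for Sobel gradients")
  ii <- 2:(R - 1); jj <- 2:(S - 1)
  p <- function(di, dj) xi[ii + di, jj + dj, drop = FALSE]
  h <- p(1, 1) + 2 * p(1, 0) + p(1, -1) - p(-1, -1) - 2 * p(-1, 0) - p(-1, 1)
  v <- p(1, 1) + 2 * p(0, 1) + p(-1, 1) - p(-1, -1) - 2 * p(0, -1) - p(1, -1)
  out <- matrix(0, R, S)
  out[ii, jj] <- sqrt(h^2 + v^2)
  out
}

#' Edge intensity and edgel count
#'
#' `E` is the sum of all Sobel magnitudes; an edgel is a pixel whose
#' magnitude strictly exceeds the threshold `tau`.
#'
#' @param mag magnitude map from [sobel_magnitude()].
#' @param tau edgel threshold on the `[0, 1]`-scaled magnitude
#'   (default 0.08, roughly 20 grey levels on an 8-bit scale).
#' @return list with `edge_intensity` and integer `n_edgels`.
#' @export
edge_metrics <- function(mag, tau = 0.08) {
  stopifnot(tau >= 0)
  list(edge_intensity = sum(mag), n_edgels = sum(mag > tau))
}

#' Histogram entropy of an intensity channel, in bits
#'
#' Shannon entropy of the pixel histogram over `bins` uniform bins on
#' `[0, 1]` (the final bin is right-closed so 1.0 lands in bin `bins`).
#'
#' @param xi intensity matrix with values in `[0, 1]`.
#' @param bins number of histogram bins (default 256).
#' @return entropy in bits, in `[0, log2(bins)]`.
#' @export
shannon_entropy <- function(xi, bins = 256) {
  stopifnot(bins >= 2)
  idx <- pmin(floor(as.vector(xi) * bins), bins - 1) + 1L
  p <- tabulate(idx, nbins = bins) / length(idx)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Composite image-quality objective
#'
#' Scores an (enhanced) intensity channel as
#' `Ox = ln(ln(E)) * n_edgels * H / (R * S)`, combining Sobel edge intensity
#' `E` (double log, so very large edge sums cannot dominate and drive
#' over-stretching), the edgel count, and the histogram entropy `H` in bits.
#' Degenerate channels (E <= e, no edgels, or zero entropy) score 0 so the
#' inner logarithms are never evaluated out of domain and a maximiser simply
#' never prefers them.
#'
#' @param xi intensity matrix in `[0, 1]`.
#' @param tau edgel threshold, see [edge_metrics()].
#' @param bins entropy histogram bins, see [shannon_entropy()].
#' @return object of class `objective_breakdown`: list with `edge_intensity`,
#'   `n_edgels`, `entropy`, `rows`, `cols`, `score`.
#' @export
#' @examples
#' xi <- matrix(runif(400), 20, 20)
#' objective_score(xi)$score
objective_score <- function(xi, tau = 0.08, bins = 256) {
  mag <- sobel_magnitude(xi)
  em <- edge_metrics(mag, tau)
  H <- shannon_entropy(xi, bins)
  R <- nrow(xi); S <- ncol(xi)
  score <- if (em$edge_intensity > exp(1) && em$n_edgels > 0 && H > 0)
    log(log(em$edge_intensity)) * em$n_edgels * H / (R * S)
  else 0
  structure(list(edge_intensity = em$edge_intensity,
                 n_edgels = em$n_edgels,
                 entropy = H, rows = R, cols = S, score = score),
            class = "objective_breakdown")
}

#' @export
print.objective_breakdown <- function(x, ...) {
  cat(sprintf("objective breakdown (%d x %d): E = %.4g, n_edgels = %d, H = %.4f bits, Ox = %.6f\n",
              x$rows, x$cols, x$edge_intensity, x$n_edgels, x$entropy, x$score))
  invisible(x)
}

#' Build a cached objective evaluator for one image
#'
#' Precomputes the local statistics of the channel once and returns a
#' function mapping a parameter vector to the objective score of the
#' enhanced channel. Identical candidates (up to 6 decimals) are served
#' from a cache; optionally every requested candidate is recorded, which
#' the feasibility tests use to audit that optimisers only ever evaluate
#' in-bounds vectors.
#'
#' @param xi intensity matrix in `[0, 1]`.
#' @param k local window size for [local_stats()].
#' @param tau,bins objective settings, see [objective_score()].
#' @param eps gain denominator guard, see [enhance_intensity()].
#' @param cache cache repeated candidates (default TRUE).
#' @param record keep a log of every requested parameter vector.
#' @return function `f(params) -> score`, with the bookkeeping environment
#'   retrievable via [evaluator_info()].
#' @export
make_evaluator <- function(xi, k = 7, tau = 0.08, bins = 256, eps = 1e-6,
                           cache = TRUE, record = FALSE) {
  stats <- local_stats(xi, k)
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv(), hash = TRUE)
  env$n_evals <- 0L
  env$n_requests <- 0L
  env$candidates <- if (record) list() else NULL
  fn <- function(params) {
    env$n_requests <- env$n_requests + 1L
    if (record) env$candidates[[length(env$candidates) + 1L]] <- params
    key <- paste(sprintf("%.6f", params), collapse = ",")
    if (cache && !is.null(env$cache[[key]])) return(env$cache[[key]])
    g <- enhance_intensity(xi, params, stats, eps)
    s <- objective_score(g, tau, bins)$score
    env$n_evals <- env$n_evals + 1L
    if (cache) env$cache[[key]] <- s
    s
  }
  attr(fn, "env") <- env
  attr(fn, "stats") <- stats
  fn
}

#' Inspect an evaluator's bookkeeping
#'
#' @param evaluator function returned by [make_evaluator()].
#' @return list with `n_evals` (distinct objective computations),
#'   `n_requests` (all calls), and `candidates` (matrix of requested
#'   parameter vectors if recording was enabled, else NULL).
#' @export
evaluator_info <- function(evaluator) {
  env <- attr(evaluator, "env")
  cand <- if (!is.null(env$candidates) && length(env$candidates))
    do.call(rbind, env$candidates) else NULL
  list(n_evals = env$n_evals, n_requests = env$n_requests, candidates = cand)
}
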