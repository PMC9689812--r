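#' Segmentation overlap metrics
#'
#' Confusion counts and the derived Jaccard (IoU) and Dice (F1) overlap
#' between a predicted and a ground-truth binary mask:
#' `Jaccard = TP / (TP + FP + FN)` and `Dice = 2 P R / (P + R)` with
#' precision `P = TP / (TP + FP)` and recall `R = TP / (TP + FN)`.
#' Conventions for empty masks: both empty scores 1 on every metric; one
#' empty scores 0.
#'
#' @param pred,truth logical (or 0/1) matrices of identical dimension.
#' @return object of class `overlap_score` with `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `jaccard`, `dice`.
#' @export
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
#' overlap_score(a, a)$dice
overlap_score <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shape mismatch")
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  if (tp + fp + fn == 0) {                      # both masks empty
    precision <- recall <- jaccard <- dice <- 1
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    jaccard <- tp / (tp + fp + fn)
    dice <- 2 * tp / (2 * tp + fp + fn)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall,
                 jaccard = jaccard, dice = dice),
            class = "overlap_score")
}

#' @export
print.overlap_score <- function(x, ...) {
  cat(sprintf("overlap: TP %d FP %d FN %d TN %d | Jaccard %.4f Dice %.4f\n",
              x$tp, x$fp, x$fn, x$tn, x$jaccard, x$dice))
  invisible(x)
}

#' Otsu threshold of an intensity channel
#'
#' Global threshold maximising the between-class variance of the histogram
#' over `bins` uniform bins on `[0, 1]`. Returns the upper edge of the last
#' bin assigned to the dark class; pixels strictly below it are "dark".
#' The first maximising cut wins on ties.
#'
#' @param xi intensity matrix with values in `[0, 1]`, not constant.
#' @param bins histogram bins (default 256).
#' @return threshold in `(0, 1)`.
#' @export
otsu_threshold <- function(xi, bins = 256) {
  x <- as.vector(xi)
  if (diff(range(x)) == 0) stop("constant channel has no Otsu threshold")
  idx <- pmin(floor(x * bins), bins - 1) + 1L
  counts <- tabulate(idx, nbins = bins)
  p <- counts / length(x)
  centres <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * centres)
  mu_t <- mu0[bins]
  # between-class variance for cut after bin k (classes 1..k vs k+1..bins)
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, bins)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)
  k / bins
}

#' Otsu baseline lesion segmenter
#'
#' Thresholds the channel with [otsu_threshold()], takes the darker class as
#' lesion, and keeps only its largest 4-connected component. This is a
#' deliberately simple stand-in segmenter: end-to-end tests use it so that
#' measured improvements reflect the contrast preprocessor, not a
#' segmenter's own capacity.
#'
#' @param xi intensity matrix with values in `[0, 1]`.
#' @param bins histogram bins for the threshold.
#' @return logical lesion mask. A constant channel yields an all-FALSE mask
#'   with a warning.
#' @export
otsu_mask <- function(xi, bins = 256) {
  if (diff(range(xi)) == 0) {
    warning("constant channel: returning empty mask")
    return(matrix(FALSE, nrow(xi), ncol(xi)))
  }
  t <- otsu_threshold(xi, bins)
  dark <- xi < t
  if (!any(dark)) return(dark)
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}
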