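#' Convert an RGB image to HSI colour space
#'
#' Uses the standard geometric (Gonzalez-Woods) HSI decomposition with
#' intensity defined as the plain channel mean, `I = (R + G + B) / 3`.
#' Hue is measured in radians in `[0, 2*pi)`; achromatic pixels
#' (R = G = B) get hue 0 by convention and saturation 0.
#'
#' @param img numeric array of dimension `R x S x 3` with values in
#'   `[0, 1]`; at least 3 rows and 3 columns.
#' @return list with components `hue`, `saturation`, `intensity`, each an
#'   `R x S` matrix.
#' @seealso [hsi_to_rgb()]
#' @export
#' @examples
#' img <- array(runif(3 * 4 * 3), dim = c(3, 4, 3))
#' hsi <- rgb_to_hsi(img)
#' range(hsi$intensity)
rgb_to_hsi <- function(img) {
  validate_rgb(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  intensity <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  saturation <- ifelse(intensity > 0, 1 - mn / pmax(intensity, .Machine$double.eps), 0)
  saturation <- pmin(pmax(saturation, 0), 1)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  chromatic <- den > 1e-12
  theta <- matrix(0, nrow(r), ncol(r))
  theta[chromatic] <- acos(pmin(pmax(num[chromatic] / den[chromatic], -1), 1))
  hue <- ifelse(b > g, 2 * pi - theta, theta)
  hue[!chromatic] <- 0
  list(hue = hue, saturation = saturation, intensity = intensity)
}

#' Convert an HSI image back to RGB
#'
#' Inverse of [rgb_to_hsi()] using the sector formulas of the geometric HSI
#' model. If the intensity channel has been modified (e.g. by contrast
#' enhancement) the reconstruction can leave the RGB gamut; out-of-gamut
#' values are clipped to `[0, 1]`.
#'
#' @param hsi list with `hue` (radians in `[0, 2*pi)`), `saturation` and
#'   `intensity` matrices of equal dimension, as returned by [rgb_to_hsi()].
#' @return numeric array `R x S x 3` with values in `[0, 1]`.
#' @export
hsi_to_rgb <- function(hsi) {
  h <- hsi$hue; s <- hsi$saturation; i <- hsi$intensity
  stopifnot(is.matrix(h), all(dim(h) == dim(s)), all(dim(h) == dim(i)))
  if (!all(is.finite(h)) || !all(is.finite(s)) || !all(is.finite(i)))
    stop("non-finite HSI values")
  h <- h %% (2 * pi)
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  third <- 2 * pi / 3

  sec1 <- h < third
  sec2 <- h >= third & h < 2 * third
  sec3 <- h >= 2 * third

  # chromatic point at angle hp within a sector: base channel I(1-S),
  # leading channel I(1 + S cos(hp)/cos(pi/3 - hp)), third closes the mean
  lead <- function(i, s, hp) i * (1 + s * cos(hp) / cos(pi / 3 - hp))

  b[sec1] <- (i * (1 - s))[sec1]
  r[sec1] <- lead(i, s, h)[sec1]
  g[sec1] <- (3 * i)[sec1] - r[sec1] - b[sec1]

  hp2 <- h - third
  r[sec2] <- (i * (1 - s))[sec2]
  g[sec2] <- lead(i, s, hp2)[sec2]
  b[sec2] <- (3 * i)[sec2] - r[sec2] - g[sec2]

  hp3 <- h - 2 * third
  g[sec3] <- (i * (1 - s))[sec3]
  b[sec3] <- lead(i, s, hp3)[sec3]
  r[sec3] <- (3 * i)[sec3] - g[sec3] - b[sec3]

  out <- array(0, dim = c(nrow(h), ncol(h), 3))
  out[, , 1] <- pmin(pmax(r, 0), 1)
  out[, , 2] <- pmin(pmax(g, 0), 1)
  out[, , 3] <- pmin(pmax(b, 0), 1)
  out
}

validate_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("expected an R x S x 3 RGB array")
  if (dim(img)[1] < 3 || dim(img)[2] < 3)
    stop("image must be at least 3 x 3")
  if (!all(is.finite(img)))
    stop("non-finite pixel values")
  if (min(img) < 0 || max(img) > 1)
    stop("RGB values must lie in [0, 1]")
  invisible(TRUE)
}
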