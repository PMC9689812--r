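#' Specification for a synthetic lesion image
#'
#' Describes a soft-edged elliptical "lesion" on a skin-toned background
#' with optional Gaussian pixel noise and a smooth illumination gradient —
#' the features that make real dermoscopy images hard for global
#' thresholding: weak lesion/skin contrast and uneven lighting. Generated
#' images are fully determined by the seed.
#'
#' @param rows,cols image size in pixels (>= 16).
#' @param center lesion centre `(row, col)`; default image centre.
#' @param axes ellipse semi-axes in pixels; default `(0.30, 0.22) *
#'   min(rows, cols)`.
#' @param rotation ellipse rotation in radians.
#' @param skin_intensity background base intensity in `[0, 1]`.
#' @param contrast_gap how much darker the lesion core is than the
#'   surrounding skin (intensity units; >= 0, where 0 produces the
#'   degenerate near-constant image used to exercise objective guards).
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param gradient_amplitude peak-to-trough amplitude of a smooth diagonal
#'   illumination plane.
#' @param texture_amplitude amplitude of a weak sinusoidal skin texture.
#' @param hue,saturation base hue (radians) and saturation of the scene.
#' @param edge_softness logistic width of the lesion boundary in pixels.
#' @param seed RNG seed for the noise.
#' @return list of class `lesion_spec`.
#' @export
lesion_spec <- function(rows = 96, cols = 96, center = NULL, axes = NULL,
                        rotation = pi / 6, skin_intensity = 0.65,
                        contrast_gap = 0.3, noise_sd = 0.02,
                        gradient_amplitude = 0.08, texture_amplitude = 0.01,
                        hue = 0.6, saturation = 0.35,
                        edge_softness = 0.25, seed = 1) {
  stopifnot(rows >= 16, cols >= 16, contrast_gap >= 0, noise_sd >= 0,
            gradient_amplitude >= 0, edge_softness > 0,
            skin_intensity >= 0, skin_intensity <= 1)
  if (is.null(center)) center <- c((rows + 1) / 2, (cols + 1) / 2)
  if (is.null(axes)) axes <- c(0.30, 0.22) * min(rows, cols)
  if (center[1] - max(axes) < 1 || center[1] + max(axes) > rows ||
      center[2] - max(axes) < 1 || center[2] + max(axes) > cols)
    stop("lesion ellipse must lie fully inside the frame")
  structure(list(rows = rows, cols = cols, center = center, axes = axes,
                 rotation = rotation, skin_intensity = skin_intensity,
                 contrast_gap = contrast_gap, noise_sd = noise_sd,
                 gradient_amplitude = gradient_amplitude,
                 texture_amplitude = texture_amplitude,
                 hue = hue, saturation = saturation,
                 edge_softness = edge_softness, seed = seed),
            class = "lesion_spec")
}

#' Generate a synthetic lesion image with ground-truth mask
#'
#' Builds the intensity plane (skin base, darker elliptical lesion with a
#' logistic soft edge, illumination gradient, texture, noise), clips to
#' `[0, 1]`, and colours it through [hsi_to_rgb()] with the constant base
#' hue/saturation. The binary truth mask marks pixels inside the ellipse.
#'
#' @param spec a [lesion_spec()].
#' @return list with `image` (`R x S x 3` array), `mask` (logical matrix)
#'   and the `spec`.
#' @export
#' @examples
#' fx <- make_lesion_image(lesion_spec(rows = 48, cols = 48, seed = 7))
#' mean(fx$mask)
make_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  set.seed(spec$seed)
  R <- spec$rows; S <- spec$cols
  rowi <- matrix(seq_len(R), R, S)
  coli <- matrix(seq_len(S), R, S, byrow = TRUE)
  dy <- rowi - spec$center[1]
  dx <- coli - spec$center[2]
  ct <- cos(spec$rotation); st <- sin(spec$rotation)
  u <- (dx * ct + dy * st) / spec$axes[1]
  v <- (-dx * st + dy * ct) / spec$axes[2]
  d <- sqrt(u^2 + v^2)
  # signed pixel distance to the ellipse boundary (approximate), logistic edge
  d_px <- (d - 1) * min(spec$axes)
  w <- plogis(-d_px / spec$edge_softness)

  grad <- spec$gradient_amplitude *
    (((rowi - 1) / max(R - 1, 1) + (coli - 1) / max(S - 1, 1)) / 2 - 0.5)
  texture <- spec$texture_amplitude *
    sin(2 * pi * rowi / 9) * cos(2 * pi * coli / 13)
  noise <- if (spec$noise_sd > 0) matrix(rnorm(R * S, 0, spec$noise_sd), R, S)
           else matrix(0, R, S)

  intensity <- spec$skin_intensity - spec$contrast_gap * w +
    grad + texture + noise
  intensity <- pmin(pmax(intensity, 0), 1)

  hsi <- list(hue = matrix(spec$hue, R, S),
              saturation = matrix(spec$saturation, R, S),
              intensity = intensity)
  list(image = hsi_to_rgb(hsi), mask = d <= 1, spec = spec)
}

#' Study conditions for a low-contrast lesion fixture
#'
#' The regime in which global thresholding genuinely struggles and contrast
#' preprocessing matters: a lesion only 8 intensity-percent darker than the
#' surrounding skin, an illumination drift across the frame 2.5x larger
#' than that gap, and 3 percent Gaussian sensor noise. Used by the
#' end-to-end improvement experiments.
#'
#' @param seed RNG seed for the fixture.
#' @param rows,cols image size.
#' @return a [lesion_spec()].
#' @export
low_contrast_lesion_spec <- function(seed, rows = 64, cols = 64) {
  lesion_spec(rows = rows, cols = cols, skin_intensity = 0.6,
              contrast_gap = 0.08, gradient_amplitude = 0.20,
              noise_sd = 0.03, seed = seed)
}

#' Compress an image's intensity contrast toward its mean
#'
#' The intensity channel is mapped to `m + factor * (xi - m)` around its
#' global mean `m`; hue and saturation are untouched. `factor = 1` leaves
#' the image unchanged; smaller factors shrink the intensity standard
#' deviation proportionally.
#'
#' @param img `R x S x 3` RGB array in `[0, 1]`.
#' @param factor contrast factor in `(0, 1]`.
#' @return degraded RGB array.
#' @export
degrade_contrast <- function(img, factor) {
  stopifnot(factor > 0, factor <= 1)
  hsi <- rgb_to_hsi(img)
  m <- mean(hsi$intensity)
  hsi$intensity <- m + factor * (hsi$intensity - m)
  hsi_to_rgb(hsi)
}
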