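#' Read an image file as an RGB array
#'
#' Supports PNG, JPEG and TIFF by file extension. Greyscale images are
#' expanded to three identical channels; an alpha channel is dropped.
#'
#' @param path file path.
#' @return numeric `R x S x 3` array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF files")
      tiff::readTIFF(path)
    },
    stop("unsupported image extension: ", ext)
  )
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] >= 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3))
  pmin(pmax(img, 0), 1)
}

#' Write an RGB array as an 8-bit PNG
#'
#' @param img numeric `R x S x 3` array in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Downsample an image so its longest side fits a budget
#'
#' Bilinear resize (via EBImage) applied per channel when the longest side
#' exceeds `max_side`; smaller images pass through untouched.
#'
#' @param img `R x S x 3` array in `[0, 1]`.
#' @param max_side maximum allowed longest side in pixels.
#' @return possibly resized array, values clipped to `[0, 1]`.
#' @export
resize_max_side <- function(img, max_side = 512) {
  d <- dim(img)
  if (max(d[1:2]) <= max_side) return(img)
  sc <- max_side / max(d[1:2])
  nr <- max(3L, as.integer(round(d[1] * sc)))
  nc <- max(3L, as.integer(round(d[2] * sc)))
  out <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3)
    out[, , ch] <- EBImage::resize(img[, , ch], w = nr, h = nc)
  pmin(pmax(out, 0), 1)
}
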