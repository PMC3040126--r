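#' Read an 8-bit RGB spot image
#'
#' Reads a PNG or TIFF brightfield image and returns it as an `h x w x 3`
#' numeric array of 0..255 values. An alpha channel is dropped; grayscale
#' images are rejected (the algorithm needs colour to unmix stains).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric `h x w x 3` array, values in 0..255.
#' @export
read_spot_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)")
  )
  d <- dim(img)
  if (is.null(d) || length(d) == 2L || d[3] < 3L) {
    stop("grayscale input not supported; expected an RGB image: ", path)
  }
  if (d[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an 8-bit RGB image to PNG
#'
#' @param img Numeric `h x w x 3` array, values in 0..255.
#' @param path Output path (`.png`).
#' @export
write_spot_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, target = path)
  invisible(path)
}
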