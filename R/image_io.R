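# Raster image input/output (PNG and TIFF, 8/16-bit or float).
#
# All images live in memory as numeric arrays in [0, 1]: H x W matrices for
# grayscale, H x W x 3 arrays for RGB, first index = row (top to bottom).

#' Read an image as an RGB array
#'
#' @param path PNG or TIFF file.
#' @return numeric H x W x 3 array in [0, 1]; grayscale files are
#'   replicated across the three channels, alpha channels are dropped.
#' @export
readImageRGB <- function(path) {
  img <- readRaster(path)
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3L))
  if (dim(img)[3] == 1L) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3L))
  img
}

#' Read an image as a single grayscale matrix
#'
#' Multi-channel files are reduced by averaging the colour channels.
#' @param path PNG or TIFF file.
#' @return numeric matrix in [0, 1].
#' @export
readImageGray <- function(path) {
  img <- readRaster(path)
  if (is.matrix(img)) return(img)
  if (dim(img)[3] >= 3L)
    return((img[, , 1] + img[, , 2] + img[, , 3]) / 3)
  img[, , 1]
}

# Dispatch on file extension; returns matrix or H x W x C array in [0, 1].
#' @noRd
readRaster <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file '%s' not found", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)",
                 ext)))
  normalizeIntensity(img)
}

#' Write an RGB or grayscale image as PNG
#'
#' @param img matrix or H x W x 3 array with values in [0, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Export a density map as 32-bit float TIFF
#'
#' Keeps the raw objects-per-pixel values (no rescaling), so external
#' viewers show the same densities the counts are summed from.
#'
#' @param d a [DensityMap-class] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDensityTiff <- function(d, path) {
  v <- if (is(d, "DensityMap")) d@values else d
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
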