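#' Read an RGB image
#'
#' Reads a PNG, TIFF, or JPEG raster and returns it as a numeric
#' `height x width x 3` array on the 0--255 scale, the working
#' representation used throughout the package. Grayscale inputs are
#' replicated across the three channels; an alpha channel, if present,
#' is dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return Numeric array `h x w x 3`, values in `[0, 255]`.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = read_tiff_checked(path),
    jpg  = ,
    jpeg = read_jpeg_checked(path),
    stop("unsupported image format '.", ext, "' (supported: png, tiff, jpeg)")
  )
  as_rgb255(img)
}

read_tiff_checked <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF requires the 'tiff' package")
  tiff::readTIFF(path)
}

read_jpeg_checked <- function(path) {
  if (!requireNamespace("jpeg", quietly = TRUE))
    stop("reading JPEG requires the 'jpeg' package")
  jpeg::readJPEG(path)
}

# normalize any decoded raster (0-1 floats, 2d gray, 4-channel RGBA)
# to h x w x 3 doubles on 0-255
as_rgb255 <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L) stop("expected a 2-D or 3-D raster")
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L) stop("expected 1, 3 or 4 channels, got ", dim(img)[3])
  img <- img * 255
  storage.mode(img) <- "double"
  img
}

#' Write an RGB image losslessly
#'
#' Writes a `h x w x 3` array (0--255 scale) as 8-bit PNG. Values are
#' clipped to `[0, 255]` and rounded; PNG is used for all pipeline output
#' so repeated ΔE evaluation is not confounded by lossy recompression.
#'
#' @param image Numeric array `h x w x 3`, 0--255 scale.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  img <- pmin(pmax(image, 0), 255) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Write a binary mask as single-channel PNG
#'
#' Masked pixels are written as 255, unmasked as 0, the convention
#' consumed by external mosaicking software.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path Path to a single-channel PNG written by [write_mask()].
#' @return Logical matrix (`TRUE` = masked).
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# flatten h x w x 3 -> (h*w) x 3 and back
flatten_rgb <- function(image) {
  d <- dim(image)
  matrix(image, nrow = d[1] * d[2], ncol = 3L)
}

unflatten_rgb <- function(mat, dims) {
  array(mat, dim = c(dims[1], dims[2], 3L))
}
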