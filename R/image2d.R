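#' @include AllClasses.R
NULL

#' Construct a 2D image
#'
#' @param pixels matrix (grayscale) or array with 3rd dimension 1, 3 or 4;
#'   values in [0,1] (clamped).
#' @param pixelSize numeric(2) physical pixel size (default 1,1).
#' @return an \linkS4class{Image2D}.
#' @export
image2d <- function(pixels, pixelSize = c(1, 1)) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) == 3L && dim(pixels)[3L] == 1L) {
    pixels <- array(pixels, dim(pixels)[1:2])
  }
  pixels[] <- pmin(pmax(pixels, 0), 1)
  new("Image2D", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Pixel data of an image
#' @param x an \linkS4class{Image2D}.
#' @return the pixel array (rows x cols[, channels]).
#' @export
imagePixels <- function(x) x@pixels

#' Number of channels of an image
#' @param x an \linkS4class{Image2D}.
#' @return 1, 3 or 4.
#' @export
imageChannels <- function(x) {
  d <- dim(x@pixels)
  if (length(d) == 2L) 1L else d[3L]
}

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Image2D %dx%d, %d channel(s)\n", d[1], d[2],
              if (length(d) == 2L) 1L else d[3L]))
})

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@frames[[1]]@pixels)
  cat(sprintf("ImageSeries of %d frames (%dx%d), current %d\n",
              length(object@frames), d[1], d[2], object@currentIndex))
})

#' Read a 2D image (PNG, TIFF or JPEG)
#'
#' Pixel values are normalized to [0,1] (8-bit gray value v maps to v/255).
#'
#' @param path path to a .png, .tif/.tiff or .jpg/.jpeg file.
#' @return an \linkS4class{Image2D}.
#' @export
readImage2d <- function(path) {
  if (!file.exists(path)) atkStop("not_found", "image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    atkStop("format", "unsupported 2D image format: %s", path))
  image2d(px)
}

#' Write a 2D image as PNG
#'
#' @param image an \linkS4class{Image2D} or a numeric array in [0,1].
#' @param path output .png path.
#' @return the path, invisibly.
#' @export
writeImage2d <- function(image, path) {
  px <- if (is(image, "Image2D")) image@pixels else image
  png::writePNG(px, path)
  invisible(path)
}

#' Read an ordered series of same-sized 2D images
#'
#' @param paths character vector of image paths, in display order.
#' @return an \linkS4class{ImageSeries} with \code{currentIndex} 1.
#' @export
readImageSeries <- function(paths) {
  frames <- lapply(paths, readImage2d)
  dims <- lapply(frames, function(f) dim(f@pixels)[1:2])
  ok <- vapply(dims, identical, logical(1), dims[[1L]])
  if (!all(ok)) {
    atkStop("validation", "series frames differ in size: %s",
            paste(basename(paths[!ok]), collapse = ", "))
  }
  imageSeries(frames)
}

#' Construct an image series from frames
#'
#' @param frames list of \linkS4class{Image2D} with identical dimensions.
#' @param currentIndex 1-based current frame (default 1).
#' @return an \linkS4class{ImageSeries}.
#' @export
imageSeries <- function(frames, currentIndex = 1L) {
  new("ImageSeries", frames = frames, currentIndex = as.integer(currentIndex))
}
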