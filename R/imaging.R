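## Images are plain numeric arrays on the 0..255 intensity scale:
## a GrayImage is a height x width matrix, an RGBImage a height x width x 3
## array. Luminance stays real-valued (never requantized to 8 bit) through
## the pipeline so that medians are not biased by rounding.

#' Load a raster image
#'
#' Reads PNG, TIFF or JPEG into a numeric array on the `[0, 255]` scale.
#' 16-bit inputs are rescaled to `[0, 255]`; an alpha channel, if present,
#' is dropped.
#'
#' @param path image file (format inferred from the extension).
#' @param asGray if `TRUE`, colour images are converted with [toLuminance()]
#'   using `mode`.
#' @param mode luminance mode passed to [toLuminance()].
#' @return a GrayImage matrix or an RGBImage `height x width x 3` array.
#' @export
loadImage <- function(path, asGray = FALSE, mode = "red_only") {
  if (!file.exists(path)) stopIO("io", sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(switch(ext,
      png = png::readPNG(path),
      tif = , tiff = tiff::readTIFF(path),
      jpg = , jpeg = jpeg::readJPEG(path),
      stopIO("io", sprintf("unsupported image format: .%s", ext))),
    error = function(e) {
      if (inherits(e, "microspotError")) stop(e)
      stopIO("io", sprintf("cannot decode %s: %s", path, conditionMessage(e)))
    })
  ## readPNG/readTIFF/readJPEG return [0,1] doubles regardless of bit depth
  img <- raw * 255
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc == 2L) img <- img[, , 1L]                   # gray + alpha
    else if (nc == 4L) img <- img[, , 1:3]             # drop alpha
    else if (nc != 3L)
      stopIO("io", sprintf("unsupported channel count: %d", nc))
  }
  if (length(dim(img)) == 3L && asGray) img <- toLuminance(img, mode)
  img
}

#' Convert an RGB image to one luminance channel
#'
#' Three conventions are supported. With a long-pass emission filter in
#' front of the camera the fluorescence signal is confined to the red sensor
#' channel, so `"red_only"` is the default; `"rec601"`
#' (`Y = 0.299 R + 0.587 G + 0.114 B`) gives a generic luminance and
#' `"equal"` the plain channel mean.
#'
#' @param img RGBImage array (`height x width x 3`, values in `[0, 255]`).
#' @param mode one of `"red_only"`, `"rec601"`, `"equal"`.
#' @return a GrayImage matrix.
#' @examples
#' px <- array(c(255, 0, 0), c(1, 1, 3))
#' toLuminance(px, "rec601")  # 76.245
#' @export
toLuminance <- function(img, mode = c("red_only", "rec601", "equal")) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stopConfig("io", "toLuminance expects a height x width x 3 array")
  mode <- match.arg(mode)
  w <- switch(mode,
    red_only = c(1, 0, 0),
    rec601 = c(0.299, 0.587, 0.114),
    equal = c(1, 1, 1) / 3)
  out <- img[, , 1L] * w[1L] + img[, , 2L] * w[2L] + img[, , 3L] * w[3L]
  matrix(out, dim(img)[1L], dim(img)[2L])
}

#' Write a grayscale image as PNG
#'
#' Intensities are clipped to `[0, 255]` and written as 8-bit grayscale.
#' Used for debug output of intermediate pipeline images.
#'
#' @param img GrayImage matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGrayPNG <- function(img, path) {
  png::writePNG(pmax(pmin(img / 255, 1), 0), path)
  invisible(path)
}

## internal: bilinear sample of a matrix at 0-based (x, y) positions;
## out-of-bounds neighbours contribute the fill value.
.sampleBilinear <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  px <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- rep(fill, length(xi))
    if (any(ok)) v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  (1 - fy) * ((1 - fx) * px(x0, y0) + fx * px(x0 + 1, y0)) +
    fy * ((1 - fx) * px(x0, y0 + 1) + fx * px(x0 + 1, y0 + 1))
}

.sampleNearest <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  xi <- round(x); yi <- round(y)
  ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
  v <- rep(fill, length(xi))
  if (any(ok)) v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
  v
}
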