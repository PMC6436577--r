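# PNG / TIFF reading and writing.
#
# Only the two web-bitmap formats are supported; DICOM and clinical metadata
# are out of scope.  Files are decoded to the 8-bit [0, 255] convention:
# 16-bit inputs are linearly rescaled (x * 255 / 65535) with a message noting
# the rescale.  RGBA inputs are accepted only when the alpha channel is fully
# opaque, in which case it is dropped.

#' Load a PNG or TIFF image
#'
#' Single-channel files load as a [raster_image()], three-channel files as a
#' [color_image()]; both use the 8-bit `[0, 255]` range.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a `raster_image` or `color_image`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG and TIFF only): ", path)
  )
  # png/tiff decode to doubles in [0,1]; recover the stored integer scale.
  bits <- attr(arr, "bits.per.sample") %||% NULL
  if (is.null(bits)) {
    # readPNG gives x/255 for 8-bit and x/65535 for 16-bit files; detect
    # 16-bit content by values that are not multiples of 1/255.
    q <- arr * 255
    bits <- if (max(abs(q - round(q))) > 1e-6) 16L else 8L
  }
  if (bits > 8L) {
    message("rescaled ", bits, "-bit image to 8-bit: ", path)
  }
  px <- arr * 255  # [0,1] decode -> [0,255]; for 16-bit this is the rescale
  if (length(dim(px)) == 2L) {
    return(raster_image(px, range = "8bit"))
  }
  nch <- dim(px)[3L]
  if (nch == 1L) {
    return(raster_image(px[, , 1L], range = "8bit"))
  }
  if (nch == 4L) {
    if (min(px[, , 4L]) >= 255 - 1e-9) {
      px <- px[, , 1:3, drop = FALSE]
      nch <- 3L
    } else {
      stop("unsupported channel count: 4 (RGBA with non-opaque alpha): ", path)
    }
  }
  if (nch != 3L) stop("unsupported channel count: ", nch, ": ", path)
  color_image(px, range = "8bit")
}

#' Write an image as PNG or TIFF
#'
#' @param img a [raster_image()] or [color_image()]; values are written at
#'   8-bit depth (unit-range images are scaled by 255).
#' @param path output path; format chosen from the extension.
#' @return invisibly, `path`.
#' @export
save_image <- function(img, path) {
  img <- to_8bit(img)
  arr <- unclass(img) / 255
  attributes(arr) <- list(dim = dim(unclass(img)))
  arr <- pmin(pmax(arr, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, target = path),
    tif = ,
    tiff = tiff::writeTIFF(arr, where = path, bits.per.sample = 8L),
    stop("unsupported output format '.", ext, "' (PNG and TIFF only)")
  )
  invisible(path)
}
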