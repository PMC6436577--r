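# Image containers.
#
# A raster_image is a plain numeric matrix (rows = image rows, row 1 at the
# top, 0-based pixel coordinates in all documentation) carrying a declared
# value range: "8bit" for [0, 255] or "unit" for [0, 1].  A color_image is an
# M x N x 3 array (R, G, B planes) with the same range convention.  Most
# internal math works on bare matrices; the classes exist to make the range
# explicit at module boundaries.

#' Create a single-channel raster image
#'
#' @param pixels numeric matrix, at least 2x2, all values finite.
#' @param range `"8bit"` (values in \[0, 255\]) or `"unit"` (values in
#'   \[0, 1\]).
#' @return the matrix with class `raster_image` and attribute `range`.
#' @export
raster_image <- function(pixels, range = c("8bit", "unit")) {
  range <- match.arg(range)
  pixels <- as.matrix(pixels)
  validate_raster(pixels, range)
  structure(pixels, range = range, class = c("raster_image", class(pixels)))
}

#' Create a three-channel color image
#'
#' @param planes M x N x 3 numeric array, or a list of three equal-shape
#'   matrices (R, G, B).
#' @inheritParams raster_image
#' @return the array with class `color_image` and attribute `range`.
#' @export
color_image <- function(planes, range = c("8bit", "unit")) {
  range <- match.arg(range)
  if (is.list(planes)) {
    stopifnot(length(planes) == 3L)
    planes <- array(c(planes[[1L]], planes[[2L]], planes[[3L]]),
                    dim = c(dim(planes[[1L]]), 3L))
  }
  stopifnot(length(dim(planes)) == 3L, dim(planes)[3L] == 3L)
  for (ch in 1:3) validate_raster(planes[, , ch], range)
  structure(planes, range = range, class = c("color_image", class(planes)))
}

validate_raster <- function(px, range) {
  if (nrow(px) < 2L || ncol(px) < 2L) stop("image must be at least 2x2")
  if (!all(is.finite(px))) stop("image contains non-finite values")
  hi <- if (range == "8bit") 255 else 1
  if (min(px) < 0 || max(px) > hi) {
    stop("values outside the declared ", range, " range [0, ", hi, "]")
  }
  invisible(px)
}

value_range <- function(img) attr(img, "range") %||% "8bit"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip classes/attributes; accept raster_image, bare matrix, or color plane.
as_pixel_matrix <- function(img) {
  if (inherits(img, "color_image")) {
    stop("expected a single-channel image, got a color_image")
  }
  m <- unclass(img)
  attr(m, "range") <- NULL
  as.matrix(m)
}

# Channels of a color image as bare matrices.
channel <- function(img, ch) {
  m <- unclass(img)[, , ch]
  as.matrix(m)
}

image_dim <- function(img) dim(unclass(img))[1:2]

# Rescale between the "8bit" and "unit" conventions.
to_unit <- function(img) {
  if (value_range(img) == "unit") return(img)
  if (inherits(img, "color_image")) {
    color_image(unclass(img) / 255, range = "unit")
  } else {
    raster_image(as_pixel_matrix(img) / 255, range = "unit")
  }
}

to_8bit <- function(img) {
  if (value_range(img) == "8bit") return(img)
  if (inherits(img, "color_image")) {
    color_image(unclass(img) * 255, range = "8bit")
  } else {
    raster_image(as_pixel_matrix(img) * 255, range = "8bit")
  }
}

#' Affinely rescale an image to the unit interval
#'
#' Maps pixel values by `x -> (x - min) / (max - min)`.  A constant image
#' maps to all zeros (the convention used for PCNN stimuli, which must be
#' bounded in \[0, 1\]).
#'
#' @param img numeric matrix or [raster_image()].
#' @return list with `pixels` (matrix in \[0, 1\]), and the recorded `min`
#'   and `max` of the input for inversion.
#' @export
#' @examples
#' normalize_intensity(matrix(c(10, 30, 20, 40), 2))$pixels
normalize_intensity <- function(img) {
  x <- as_pixel_matrix(img)
  stopifnot(all(is.finite(x)))
  lo <- min(x); hi <- max(x)
  px <- if (hi > lo) (x - lo) / (hi - lo) else matrix(0, nrow(x), ncol(x))
  list(pixels = px, min = lo, max = hi)
}

#' Validate that two images form a registered pair
#'
#' The fusion pipeline assumes its inputs are pre-registered; this check only
#' enforces identical pixel grids and performs no registration.
#'
#' @param a first image (usually the SPECT [color_image()]).
#' @param b second image (usually the CT [raster_image()] or matrix).
#' @return invisibly, `list(a = a, b = b)` unchanged.
#' @export
check_registered_pair <- function(a, b) {
  da <- image_dim(a); db <- image_dim(b)
  if (!identical(da, db)) {
    stop("images are not registered: shapes ", da[1L], "x", da[2L], " vs ",
         db[1L], "x", db[2L])
  }
  invisible(list(a = a, b = b))
}
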