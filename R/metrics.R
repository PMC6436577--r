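# Reference-free fusion quality metrics.
#
# All four scores are computed on the 8-bit gray scale [0, 255]:
#   * standard deviation  sigma = sqrt( sum (Z - mean(Z))^2 / (M*N) )
#     (population divisor),
#   * mean gradient       Gbar = mean over the (M-1)x(N-1) forward-difference
#     grid of sqrt((dZ/dx^2 + dZ/dy^2) / 2),
#   * spatial frequency   SF = sqrt(RF^2 + CF^2) with
#     RF = sqrt( sum row-wise first differences squared / (M*N) ) and CF the
#     column-wise analogue,
#   * information entropy E = -sum p_i log2 p_i over the L-level gray
#     histogram (0 log 0 := 0), in bits.
# Higher values of each indicate a more informative / sharper fused image.

#' Standard deviation of an image (population divisor)
#' @param img numeric matrix or [raster_image()].
#' @return non-negative scalar, gray levels.
#' @export
std_dev <- function(img) {
  x <- as_pixel_matrix(img)
  sqrt(mean((x - mean(x))^2))
}

#' Mean gradient of an image
#'
#' Average of `sqrt((dx^2 + dy^2)/2)` over the `(M-1) x (N-1)` grid of
#' forward differences along rows (`dx`) and columns (`dy`).
#'
#' @inheritParams std_dev
#' @return non-negative scalar, gray levels per pixel.
#' @export
mean_gradient <- function(img) {
  x <- as_pixel_matrix(img)
  M <- nrow(x); N <- ncol(x)
  stopifnot(M >= 2L, N >= 2L)
  dx <- x[2:M, 1:(N - 1L), drop = FALSE] - x[1:(M - 1L), 1:(N - 1L), drop = FALSE]
  dy <- x[1:(M - 1L), 2:N, drop = FALSE] - x[1:(M - 1L), 1:(N - 1L), drop = FALSE]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Spatial frequency of an image
#'
#' @inheritParams std_dev
#' @return named vector `c(sf, rf, cf)`: total, row and column frequency,
#'   gray levels per pixel.  `sf^2 = rf^2 + cf^2`.
#' @export
spatial_frequency <- function(img) {
  x <- as_pixel_matrix(img)
  M <- nrow(x); N <- ncol(x)
  stopifnot(M >= 2L, N >= 2L)
  rf <- sqrt(sum((x[, 2:N, drop = FALSE] - x[, 1:(N - 1L), drop = FALSE])^2) / (M * N))
  cf <- sqrt(sum((x[2:M, , drop = FALSE] - x[1:(M - 1L), , drop = FALSE])^2) / (M * N))
  c(sf = sqrt(rf^2 + cf^2), rf = rf, cf = cf)
}

#' Gray-level histogram entropy of an image
#'
#' @inheritParams std_dev
#' @param levels number of gray levels `L` (default 256).
#' @param rescale quantization rule: `"auto"` (default) rounds images already
#'   on the 8-bit scale directly to `0..L-1` and min-max remaps anything else
#'   (unit-range images, signed sub-bands); `"minmax"` always remaps the
#'   observed range onto `0..L-1`; `"none"` only rounds and clamps.
#' @return entropy in bits, in `[0, log2(levels)]`.
#' @export
img_entropy <- function(img, levels = 256L, rescale = c("auto", "minmax", "none")) {
  rescale <- match.arg(rescale)
  x <- as_pixel_matrix(img)
  declared <- if (inherits(img, "raster_image")) value_range(img) else NULL
  if (rescale == "auto") {
    on_8bit <- identical(declared, "8bit") ||
      (is.null(declared) && min(x) >= 0 && max(x) <= 255 && max(x) > 1)
    rescale <- if (on_8bit) "none" else "minmax"
  }
  if (rescale == "minmax") {
    lo <- min(x); hi <- max(x)
    x <- if (hi > lo) (x - lo) / (hi - lo) * (levels - 1L) else x * 0
  }
  q <- clamp(round(x), 0, levels - 1L)
  p <- tabulate(q + 1L, nbins = levels) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' All four fusion quality metrics of an image
#'
#' Color images are scored on their IHS intensity plane rescaled to
#' \[0, 255\] (the pipeline fuses only the intensity, so that is the plane
#' the scores describe); unit-range grayscale images are rescaled by 255.
#'
#' @param img a [raster_image()], [color_image()] or numeric matrix (assumed
#'   already on the 8-bit scale).
#' @param levels gray levels for the entropy histogram.
#' @return object of class `metrics_report`: list with `sd`, `mean_gradient`,
#'   `sf`, `rf`, `cf`, `entropy`.
#' @export
#' @examples
#' fusion_metrics(matrix(c(0, 0, 255, 255), 2))
fusion_metrics <- function(img, levels = 256L) {
  if (inherits(img, "color_image")) {
    x <- rgb_to_ihs(img)$I * 255
  } else if (inherits(img, "raster_image") && value_range(img) == "unit") {
    x <- as_pixel_matrix(img) * 255
  } else {
    x <- as_pixel_matrix(img)
  }
  sf <- spatial_frequency(x)
  out <- list(sd = std_dev(x), mean_gradient = mean_gradient(x),
              sf = unname(sf["sf"]), rf = unname(sf["rf"]),
              cf = unname(sf["cf"]),
              entropy = img_entropy(x, levels = levels, rescale = "none"))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SD = %.4f  Gbar = %.4f  SF = %.4f (RF %.4f, CF %.4f)  E = %.4f bits\n",
              x$sd, x$mean_gradient, x$sf, x$rf, x$cf, x$entropy))
  invisible(x)
}
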