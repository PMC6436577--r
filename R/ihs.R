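# Linear (triangular) intensity-hue-saturation transform.
#
# The fusion pipeline replaces only the intensity plane of the SPECT image,
# so the color model must have an exact algebraic inverse.  We use the
# orthogonal linear IHS model standard in pansharpening-style fusion:
#
#   [ I  ]   [  1/3      1/3      1/3    ] [R]
#   [ v1 ] = [ -1/sq18  -1/sq18   2/sq18 ] [G]     sq18 = sqrt(18), sq2 = sqrt(2)
#   [ v2 ]   [  1/sq2   -1/sq2    0      ] [B]
#
# with hue H = atan2(v2, v1) and saturation S = sqrt(v1^2 + v2^2).  On the
# gray axis (R = G = B) both chroma coordinates vanish exactly, S = 0, and H
# is conventionally set to 0 so the inverse stays exact.

ihs_forward_matrix <- function() {
  rbind(I  = c(1, 1, 1) / 3,
        v1 = c(-1, -1, 2) / sqrt(18),
        v2 = c(1, -1, 0) / sqrt(2))
}

#' Forward IHS transform of an RGB image
#'
#' @param img a [color_image()]; 8-bit images are rescaled to \[0, 1\]
#'   internally.
#' @return an object of class `ihs_triple`: list with matrices `I`
#'   (intensity, \[0, 1\] for in-gamut input), `H` (hue angle in
#'   `(-pi, pi]`, 0 where `S = 0`) and `S` (saturation magnitude, `>= 0`).
#' @export
#' @examples
#' img <- color_image(array(runif(32 * 32 * 3), c(32, 32, 3)), range = "unit")
#' t <- rgb_to_ihs(img)
#' max(abs(unclass(ihs_to_rgb(t, clip = FALSE)) - unclass(img))) < 1e-9
rgb_to_ihs <- function(img) {
  stopifnot(inherits(img, "color_image"))
  img <- to_unit(img)
  R <- channel(img, 1L); G <- channel(img, 2L); B <- channel(img, 3L)
  M <- ihs_forward_matrix()
  I  <- M[1, 1] * R + M[1, 2] * G + M[1, 3] * B
  v1 <- M[2, 1] * R + M[2, 2] * G + M[2, 3] * B
  v2 <- M[3, 1] * R + M[3, 2] * G + M[3, 3] * B
  S <- sqrt(v1^2 + v2^2)
  H <- atan2(v2, v1)
  H[S == 0] <- 0
  structure(list(I = I, H = H, S = S), class = "ihs_triple")
}

#' Inverse IHS transform
#'
#' Exact algebraic inverse of [rgb_to_ihs()].  Fusion may push the intensity
#' plane outside the RGB gamut; out-of-range values are clipped to \[0, 1\]
#' and the number of clipped samples (over all three channels) is recorded in
#' the `clipped` attribute of the result.
#'
#' @param t an `ihs_triple`, or the `I` matrix when `H` and `S` are given.
#' @param H,S optional hue/saturation matrices when `t` is an intensity
#'   matrix.
#' @param clip clip the output into \[0, 1\] (default).  With `clip = FALSE`
#'   the raw inverse is returned (useful for round-trip checks).
#' @return a unit-range [color_image()] with attribute `clipped` (integer
#'   count of clipped samples; 0 when `clip = FALSE`).
#' @export
ihs_to_rgb <- function(t, H = NULL, S = NULL, clip = TRUE) {
  if (!inherits(t, "ihs_triple")) {
    t <- structure(list(I = as_pixel_matrix(t), H = H, S = S),
                   class = "ihs_triple")
  }
  stopifnot(!is.null(t$I), !is.null(t$H), !is.null(t$S))
  v1 <- t$S * cos(t$H)
  v2 <- t$S * sin(t$H)
  Minv <- solve(ihs_forward_matrix())
  R <- Minv[1, 1] * t$I + Minv[1, 2] * v1 + Minv[1, 3] * v2
  G <- Minv[2, 1] * t$I + Minv[2, 2] * v1 + Minv[2, 3] * v2
  B <- Minv[3, 1] * t$I + Minv[3, 2] * v1 + Minv[3, 3] * v2
  arr <- array(c(R, G, B), dim = c(dim(t$I), 3L))
  if (clip) {
    n_clip <- sum(arr < 0 | arr > 1)
    arr <- clamp(arr, 0, 1)
    out <- color_image(arr, range = "unit")
  } else {
    # unclipped values may lie outside the gamut; skip range validation
    n_clip <- 0L
    out <- structure(arr, range = "unit", class = c("color_image", "array"))
  }
  attr(out, "clipped") <- as.integer(n_clip)
  out
}
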