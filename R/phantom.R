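# Deterministic CT-like / SPECT-like head phantoms.
#
# The generator emulates the two modalities' signatures on a shared head
# mask so the whole pipeline is exercisable without clinical data:
#   * CT: a bright skull annulus (bone ~ 230) with sharp edges, a mid-gray
#     interior with low-amplitude smoothed texture, dark background;
#   * SPECT: a few smooth Gaussian activity blobs confined to the head,
#     rendered through a fixed hot-iron pseudo-color map (black -> red ->
#     yellow -> white), zero activity outside the mask.
# Everything is seeded; two calls with the same spec are identical.

#' Phantom specification
#'
#' @param size image dimensions `c(rows, cols)`.
#' @param skull_radius_frac skull annulus centre radius as a fraction of the
#'   smaller image dimension, in `(0, 0.5)`.
#' @param skull_thickness_frac annulus thickness, same units.
#' @param n_blobs number of SPECT activity blobs, `>= 1`.
#' @param blob_sigma_frac Gaussian blob standard deviation as a fraction of
#'   the smaller image dimension.
#' @param noise_sd additive Gaussian noise on the CT image, gray levels.
#' @param seed integer RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(128L, 128L), skull_radius_frac = 0.42,
                         skull_thickness_frac = 0.06, n_blobs = 3L,
                         blob_sigma_frac = 0.10, noise_sd = 0,
                         seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 16L),
            skull_radius_frac > 0, skull_radius_frac < 0.5,
            skull_thickness_frac > 0, n_blobs >= 1L,
            blob_sigma_frac > 0, noise_sd >= 0)
  structure(list(size = as.integer(size),
                 skull_radius_frac = skull_radius_frac,
                 skull_thickness_frac = skull_thickness_frac,
                 n_blobs = as.integer(n_blobs),
                 blob_sigma_frac = blob_sigma_frac,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_radius <- function(spec) {
  M <- spec$size[1L]; N <- spec$size[2L]
  ci <- (M + 1) / 2; cj <- (N + 1) / 2
  r <- sqrt(outer((seq_len(M) - ci)^2, (seq_len(N) - cj)^2, `+`)) / min(M, N)
  list(r = r,
       ring = abs(r - spec$skull_radius_frac) <= spec$skull_thickness_frac / 2,
       inner = r < spec$skull_radius_frac - spec$skull_thickness_frac / 2,
       head = r <= spec$skull_radius_frac + spec$skull_thickness_frac / 2)
}

#' Generate a CT-like phantom
#'
#' @param spec a [phantom_spec()].
#' @return an 8-bit [raster_image()].
#' @export
make_ct_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_radius(spec)
  M <- spec$size[1L]; N <- spec$size[2L]
  with_seed(spec$seed, {
    img <- matrix(10, M, N)            # background
    # interior soft tissue: mid gray plus smoothed low-amplitude texture
    tex <- matrix(rnorm(M * N), M, N)
    b <- c(1, 4, 6, 4, 1) / 16
    tex <- conv2_sym(tex, kernel_from_matrix(outer(b, b)))
    tex <- 12 * tex / max(abs(tex))
    img[g$inner] <- 80 + tex[g$inner]
    img[g$ring] <- 230                 # bone
    if (spec$noise_sd > 0) img <- img + rnorm(M * N, sd = spec$noise_sd)
    raster_image(clamp(img, 0, 255), range = "8bit")
  })
}

# Fixed hot-iron pseudo-color map on [0, 1]: black -> red -> yellow -> white.
hot_iron <- function(x) {
  list(R = clamp(3 * x, 0, 1), G = clamp(3 * x - 1, 0, 1),
       B = clamp(3 * x - 2, 0, 1))
}

#' Generate a SPECT-like phantom
#'
#' @param spec a [phantom_spec()].
#' @return an 8-bit [color_image()]; pixels outside the head mask are black.
#' @export
make_spect_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_radius(spec)
  M <- spec$size[1L]; N <- spec$size[2L]
  ci <- (M + 1) / 2; cj <- (N + 1) / 2
  rmax <- 0.7 * spec$skull_radius_frac * min(M, N)
  sigma <- spec$blob_sigma_frac * min(M, N)
  with_seed(spec$seed + 1L, {
    act <- matrix(0, M, N)
    ii <- row(act); jj <- col(act)
    for (b in seq_len(spec$n_blobs)) {
      ang <- runif(1L, 0, 2 * pi)
      rad <- sqrt(runif(1L)) * rmax
      bc <- c(ci + rad * sin(ang), cj + rad * cos(ang))
      amp <- runif(1L, 0.6, 1)
      act <- act + amp * exp(-((ii - bc[1L])^2 + (jj - bc[2L])^2) / (2 * sigma^2))
    }
    act <- act / max(act)
    act[!g$head] <- 0
    ch <- hot_iron(act)
    color_image(array(c(ch$R, ch$G, ch$B) * 255, c(M, N, 3L)), range = "8bit")
  })
}

#' Generate a registered SPECT/CT phantom pair
#'
#' Both phantoms are built on the same head mask and grid, so they are
#' registered by construction.
#'
#' @param spec a [phantom_spec()].
#' @return list with `spect` ([color_image()]) and `ct` ([raster_image()]).
#' @export
#' @examples
#' pair <- make_phantom_pair(phantom_spec(size = c(64, 64), seed = 3))
#' check_registered_pair(pair$spect, pair$ct)
make_phantom_pair <- function(spec = phantom_spec()) {
  pair <- list(spect = make_spect_phantom(spec), ct = make_ct_phantom(spec))
  check_registered_pair(pair$spect, pair$ct)
  pair
}
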