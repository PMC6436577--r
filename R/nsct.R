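# Non-subsampled contourlet transform (NSCT).
#
# Two nested undecimated filter trees:
#   * a non-subsampled pyramid (NSP): at level j the analysis pair is the
#     base pair dilated ("a trous") by 2^(j-1), splitting the running lowpass
#     into a coarser lowpass and a bandpass ring;
#   * a non-subsampled directional filter bank (NSDFB): each bandpass ring is
#     split by an n_j-stage binary tree of fan/parallelogram filter pairs
#     into 2^(n_j) directional wedges.
# No signal is ever decimated, so every sub-band keeps the source size and
# the transform is shift-invariant away from the (mirror-extended) borders.

# Upsampling matrix for NSDFB stage `s`, parent branch `k` (1-based among
# 2^(s-1)), together with which of the four sheared ("parallelogram")
# variants of the fan filter to use.  Stage 1 uses the fan itself; stage 2
# the fan on the quincunx lattice (a quadrant filter); stages >= 3 follow the
# classical DFB expansion where each quadrant is subdivided by sheared fans
# on increasingly dilated lattices.
nsdfb_branch <- function(s, k) {
  shears <- list(
    diag(2L),
    matrix(c(1L, 1L, 0L, 1L), 2, 2, byrow = TRUE),   # R1
    matrix(c(1L, -1L, 0L, 1L), 2, 2, byrow = TRUE),  # R2
    matrix(c(1L, 0L, 1L, 1L), 2, 2, byrow = TRUE),   # R3
    matrix(c(1L, 0L, -1L, 1L), 2, 2, byrow = TRUE)   # R4
  )
  Q <- matrix(c(1L, 1L, -1L, 1L), 2, 2, byrow = TRUE)
  if (s == 1L) return(diag(2L))
  if (s == 2L) return(Q)
  half <- 2L^(s - 2L)
  p <- 2L^(s - 3L)
  if (k <= half) {
    slk <- 2L * ((k - 1L) %/% 2L) - p + 1L
    mk <- 2L * matrix(c(p, 0L, 0L, 1L), 2, 2, byrow = TRUE) %*%
      matrix(c(1L, 0L, -slk, 1L), 2, 2, byrow = TRUE)
    i <- (k - 1L) %% 2L + 2L
  } else {
    kk <- k - half
    slk <- 2L * ((kk - 1L) %/% 2L) - p + 1L
    mk <- 2L * matrix(c(1L, 0L, 0L, p), 2, 2, byrow = TRUE) %*%
      matrix(c(1L, -slk, 0L, 1L), 2, 2, byrow = TRUE)
    i <- (k - 1L) %% 2L + 4L
  }
  mk %*% shears[[i]]
}

# Analysis kernel pair for one NSDFB split: the bank's fan pair upsampled by
# the branch matrix.  Complementarity (U2 = delta - U1) is preserved by any
# integer upsampling, so each split stays perfect-reconstruction.
nsdfb_pair <- function(bank, s, k, synthesis = FALSE) {
  M <- nsdfb_branch(s, k)
  if (synthesis) {
    list(a = kernel_upsample(bank$dir$V1, M), b = kernel_upsample(bank$dir$V2, M))
  } else {
    list(a = kernel_upsample(bank$dir$U1, M), b = kernel_upsample(bank$dir$U2, M))
  }
}

nsdfb_decompose <- function(x, n_stages, bank) {
  bands <- list(x)
  for (s in seq_len(n_stages)) {
    nxt <- vector("list", 2L * length(bands))
    for (k in seq_along(bands)) {
      kp <- nsdfb_pair(bank, s, k)
      nxt[[2L * k - 1L]] <- conv2_sym(bands[[k]], kp$a)
      nxt[[2L * k]] <- conv2_sym(bands[[k]], kp$b)
    }
    bands <- nxt
  }
  bands
}

nsdfb_reconstruct <- function(bands, n_stages, bank) {
  for (s in rev(seq_len(n_stages))) {
    nxt <- vector("list", length(bands) %/% 2L)
    for (k in seq_along(nxt)) {
      kp <- nsdfb_pair(bank, s, k, synthesis = TRUE)
      nxt[[k]] <- conv2_sym(bands[[2L * k - 1L]], kp$a) +
        conv2_sym(bands[[2L * k]], kp$b)
    }
    bands <- nxt
  }
  bands[[1L]]
}

# Validate a decomposition spec: J levels with dirs[j] directional stages.
check_nsct_spec <- function(spec, dim = NULL) {
  stopifnot(is.list(spec), !is.null(spec$levels), !is.null(spec$dirs))
  J <- as.integer(spec$levels)
  dirs <- as.integer(spec$dirs)
  if (J < 1L || length(dirs) != J || any(dirs < 1L)) {
    stop("invalid NSCT spec: need levels >= 1 and one dirs entry >= 1 per level")
  }
  if (!is.null(dim) && J > floor(log2(min(dim)))) {
    stop("NSCT spec with ", J, " levels is too deep for a ",
         dim[1L], "x", dim[2L], " image")
  }
  list(levels = J, dirs = dirs)
}

#' Decompose an image with the non-subsampled contourlet transform
#'
#' Splits `img` into one coarse lowpass band plus, for each pyramid level
#' `j = 1..J` (finest first), `2^dirs[j]` directional bandpass sub-bands.
#' All bands have the size of `img` (nothing is decimated) and the transform
#' is exactly invertible by [nsct_reconstruct()].  Level-`j` pyramid kernels
#' are the base kernels dilated by `2^(j-1)` (the "a trous" scheme); all
#' filtering uses symmetric (mirror) boundary extension.
#'
#' @param img numeric matrix (or [raster_image()]); any real values.
#' @param spec list with `levels` (number of pyramid levels `J >= 1`) and
#'   `dirs` (integer vector of length `J`, directional stages per level, each
#'   `>= 1`, so level `j` yields `2^dirs[j]` bands).  Default: 3 levels with
#'   `dirs = c(2, 3, 3)`.
#' @param bank filter bank from [build_filter_bank()].
#' @return an object of class `nsct_pyramid`: list with `low` (matrix),
#'   `levels` (list of lists of matrices, finest level first), `spec`,
#'   `bank_name`.
#' @export
#' @examples
#' x <- matrix(rnorm(64 * 64), 64, 64)
#' p <- nsct_decompose(x, list(levels = 2, dirs = c(1, 2)))
#' max(abs(nsct_reconstruct(p) - x)) < 1e-6
nsct_decompose <- function(img,
                           spec = list(levels = 3L, dirs = c(2L, 3L, 3L)),
                           bank = build_filter_bank()) {
  x <- as_pixel_matrix(img)
  stopifnot(all(is.finite(x)))
  sp <- check_nsct_spec(spec, dim(x))
  low <- x
  levels <- vector("list", sp$levels)
  for (j in seq_len(sp$levels)) {
    d <- 2L^(j - 1L) * diag(2L)
    H1j <- kernel_upsample(bank$pyr$H1, d)
    H2j <- kernel_upsample(bank$pyr$H2, d)
    high <- conv2_sym(low, H2j)
    low <- conv2_sym(low, H1j)
    levels[[j]] <- nsdfb_decompose(high, sp$dirs[j], bank)
  }
  out <- list(low = low, levels = levels, spec = sp, bank_name = bank$name)
  class(out) <- "nsct_pyramid"
  out
}

#' Reconstruct an image from an NSCT pyramid
#'
#' Exact inverse of [nsct_decompose()] when called with the same filter bank.
#'
#' @param pyr an `nsct_pyramid`.
#' @param bank filter bank; must be the family used for analysis.
#' @return numeric matrix with the original image's dimensions.
#' @export
nsct_reconstruct <- function(pyr, bank = build_filter_bank()) {
  stopifnot(inherits(pyr, "nsct_pyramid"))
  sp <- pyr$spec
  dm <- dim(pyr$low)
  x <- pyr$low
  for (j in rev(seq_len(sp$levels))) {
    bands <- pyr$levels[[j]]
    if (length(bands) != 2L^sp$dirs[j]) {
      stop("level ", j, " holds ", length(bands), " bands; expected ",
           2L^sp$dirs[j])
    }
    for (b in bands) {
      if (!identical(dim(b), dm)) stop("band shape mismatch inside pyramid")
    }
    high <- nsdfb_reconstruct(bands, sp$dirs[j], bank)
    d <- 2L^(j - 1L) * diag(2L)
    x <- conv2_sym(x, kernel_upsample(bank$pyr$G1, d)) +
      conv2_sym(high, kernel_upsample(bank$pyr$G2, d))
  }
  x
}
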