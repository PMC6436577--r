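# Sparse zero-phase 2-D filter kernels.
#
# Every filter in the non-subsampled transforms is represented as a set of
# integer offsets (di, dj) with real weights, i.e. the nonzero taps of a
# kernel centred on the origin.  This representation makes the two
# operations the transforms need cheap and exact:
#   * dilation / upsampling by an integer matrix M is just `offsets %*% t(M)`
#     (no zero-stuffed arrays),
#   * filtering is a short sum of shifted copies of the image.
# All built-in kernels are symmetric about the origin (zero phase), so
# correlation and convolution coincide.

#' Construct a sparse filter kernel
#'
#' @param offsets integer matrix with two columns (row offset, column offset),
#'   one row per tap.
#' @param weights numeric vector of tap weights, same length as
#'   `nrow(offsets)`.
#' @return an object of class `sf_kernel`.
#' @keywords internal
sf_kernel <- function(offsets, weights) {
  offsets <- matrix(as.integer(round(offsets)), ncol = 2L)
  stopifnot(nrow(offsets) == length(weights), all(is.finite(weights)))
  k <- list(offsets = offsets, weights = as.numeric(weights))
  class(k) <- "sf_kernel"
  kernel_simplify(k)
}

# Merge duplicate offsets and drop (numerically) zero taps.
kernel_simplify <- function(k, tol = 0) {
  key <- paste(k$offsets[, 1L], k$offsets[, 2L], sep = ",")
  agg <- rowsum(k$weights, key)          # one row per unique key, sorted
  parts <- do.call(rbind, strsplit(rownames(agg), ",", fixed = TRUE))
  off <- cbind(as.integer(parts[, 1L]), as.integer(parts[, 2L]))
  keep <- abs(agg[, 1L]) > tol
  if (!any(keep)) {                      # all-zero kernel: keep an explicit 0 tap
    off <- matrix(c(0L, 0L), ncol = 2L); w <- 0
  } else {
    off <- off[keep, , drop = FALSE]; w <- agg[keep, 1L]
  }
  out <- list(offsets = off, weights = as.numeric(w))
  class(out) <- "sf_kernel"
  out
}

#' @keywords internal
kernel_delta <- function(gain = 1) {
  sf_kernel(matrix(c(0L, 0L), ncol = 2L), gain)
}

# Dense odd-sized matrix -> sparse kernel, centre tap at the middle element.
kernel_from_matrix <- function(m) {
  stopifnot(nrow(m) %% 2L == 1L, ncol(m) %% 2L == 1L)
  ci <- (nrow(m) + 1L) %/% 2L
  cj <- (ncol(m) + 1L) %/% 2L
  idx <- which(m != 0, arr.ind = TRUE)
  sf_kernel(cbind(idx[, 1L] - ci, idx[, 2L] - cj), m[idx])
}

kernel_scale <- function(k, s) sf_kernel(k$offsets, k$weights * s)

kernel_add <- function(a, b) {
  sf_kernel(rbind(a$offsets, b$offsets), c(a$weights, b$weights))
}

# Full 2-D convolution of two kernels (polynomial product).
kernel_convolve <- function(a, b) {
  na <- nrow(a$offsets); nb <- nrow(b$offsets)
  off <- a$offsets[rep(seq_len(na), each = nb), , drop = FALSE] +
    b$offsets[rep(seq_len(nb), times = na), , drop = FALSE]
  w <- rep(a$weights, each = nb) * rep(b$weights, times = na)
  sf_kernel(off, w)
}

# Integer-power of a kernel under convolution.
kernel_power <- function(k, n) {
  out <- kernel_delta()
  for (i in seq_len(n)) out <- kernel_convolve(out, k)
  out
}

# Upsample (dilate) a kernel by an integer matrix M: each tap at offset m
# moves to M %*% m.  The frequency response becomes K(t(M) %*% omega).
kernel_upsample <- function(k, M) {
  sf_kernel(k$offsets %*% t(M), k$weights)
}

# Modulate taps along rows by (-1)^di: shifts the response by pi in the
# row-frequency axis (turns a diamond lowpass into a fan filter).
kernel_modulate_rows <- function(k) {
  sf_kernel(k$offsets, k$weights * (-1)^(k$offsets[, 1L]))
}

#' Frequency response of a sparse kernel on a regular grid
#'
#' @param k an `sf_kernel`.
#' @param n grid size; response is evaluated at `omega = 2*pi*(0:(n-1))/n`
#'   along both axes.
#' @return an `n x n` complex matrix, row index = row frequency.
#' @keywords internal
kernel_freqz <- function(k, n = 256L) {
  om <- 2 * pi * (0:(n - 1L)) / n
  H <- matrix(0 + 0i, n, n)
  for (t in seq_len(nrow(k$offsets))) {
    er <- exp(-1i * k$offsets[t, 1L] * om)
    ec <- exp(-1i * k$offsets[t, 2L] * om)
    H <- H + k$weights[t] * outer(er, ec)
  }
  H
}

# Mirror ("symmetric") boundary index vector: positions (1-pad):(n+pad)
# mapped into 1..n with edge-repeating reflection.
reflect_idx <- function(n, pad) {
  t <- (1L - pad):(n + pad)
  # fold into [1, 2n] then reflect the upper half
  m <- ((t - 1L) %% (2L * n))
  m <- ifelse(m < 0L, m + 2L * n, m)
  ifelse(m < n, m + 1L, 2L * n - m)
}

#' Filter an image with a sparse kernel under symmetric extension
#'
#' Computes `y(i,j) = sum_t w_t * x(i + di_t, j + dj_t)` with mirror
#' (edge-repeating) extension at the boundaries; output has the input's size.
#' All shipped kernels are zero phase, so this equals convolution.
#'
#' @param x numeric matrix.
#' @param k an `sf_kernel`.
#' @return filtered matrix, same dimensions as `x`.
#' @keywords internal
conv2_sym <- function(x, k) {
  M <- nrow(x); N <- ncol(x)
  pr <- max(abs(k$offsets[, 1L]), 0L)
  pc <- max(abs(k$offsets[, 2L]), 0L)
  xp <- x[reflect_idx(M, pr), reflect_idx(N, pc), drop = FALSE]
  y <- matrix(0, M, N)
  for (t in seq_len(nrow(k$offsets))) {
    di <- k$offsets[t, 1L]; dj <- k$offsets[t, 2L]
    y <- y + k$weights[t] *
      xp[(pr + 1L + di):(pr + M + di), (pc + 1L + dj):(pc + N + dj), drop = FALSE]
  }
  y
}
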