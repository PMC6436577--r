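# Perfect-reconstruction filter banks for the non-subsampled transforms.
#
# The non-subsampled pyramid needs an analysis pair {H1, H2} and a synthesis
# pair {G1, G2} with H1(w)G1(w) + H2(w)G2(w) = 1 for all w; the directional
# bank needs {U1, U2} / {V1, V2} with U1(w)V1(w) + U2(w)V2(w) = 1.  The
# built-in family satisfies both identities by construction: the highpass is
# the exact complement of the lowpass (H2 = delta - H1, U2 = delta - U1) and
# the synthesis filters are deltas, i.e. an additive ("a trous") split
#     low = H1 * x,   high = x - low,   x = low + high.

#' Construct a perfect-reconstruction NSCT filter bank
#'
#' Returns the analysis/synthesis kernel pairs used by [nsct_decompose()] and
#' [nsct_reconstruct()].  The `"maxflat"` family (the default and currently
#' the only built-in) uses:
#' \itemize{
#'   \item pyramid lowpass `H1`: separable 5x5 binomial (B-spline) kernel
#'     `outer(c(1,4,6,4,1), c(1,4,6,4,1))/256`, maximally flat at DC with
#'     `H1(0,0) = 1`; highpass `H2 = delta - H1`; synthesis `G1 = G2 = delta`.
#'   \item directional fan `U1`: a maximally-flat diamond lowpass obtained by
#'     the McClellan transform of the 7-tap halfband filter
#'     `(-1, 0, 9, 16, 9, 0, -1)/32` (as a polynomial in `cos w`:
#'     `(2 + 3x - x^3)/4` with `x -> (cos w1 + cos w2)/2`), modulated by pi
#'     along the row-frequency axis; `U2 = delta - U1`; `V1 = V2 = delta`.
#' }
#' Both perfect-reconstruction identities then hold to machine precision,
#' which [pr_residuals()] verifies on a frequency grid.
#'
#' @param name filter family identifier; `"maxflat"` is built in.
#' @return an object of class `nsct_filter_bank`: a list with elements
#'   `name`, `pyr` (kernels `H1`, `H2`, `G1`, `G2`) and `dir` (kernels
#'   `U1`, `U2`, `V1`, `V2`).
#' @export
#' @examples
#' bank <- build_filter_bank()
#' pr_residuals(bank)
build_filter_bank <- function(name = "maxflat") {
  supported <- "maxflat"
  if (!name %in% supported) {
    stop("unknown filter family '", name, "'; supported: ",
         paste(supported, collapse = ", "))
  }
  b <- c(1, 4, 6, 4, 1) / 16
  H1 <- kernel_from_matrix(outer(b, b))
  H2 <- kernel_add(kernel_delta(), kernel_scale(H1, -1))

  # Diamond maxflat lowpass via McClellan transform of the halfband filter
  # (16 + 18 cos w - 2 cos 3w)/32 = (2 + 3x - x^3)/4,  x = (cos w1 + cos w2)/2.
  Tk <- kernel_from_matrix(matrix(c(0, 0.25, 0,
                                    0.25, 0, 0.25,
                                    0, 0.25, 0), 3, 3, byrow = TRUE))
  D <- kernel_add(
    kernel_add(kernel_delta(0.5), kernel_scale(Tk, 0.75)),
    kernel_scale(kernel_power(Tk, 3L), -0.25)
  )
  U1 <- kernel_modulate_rows(D)   # fan: passband around |w1| = pi
  U2 <- kernel_add(kernel_delta(), kernel_scale(U1, -1))

  bank <- list(
    name = name,
    pyr = list(H1 = H1, H2 = H2, G1 = kernel_delta(), G2 = kernel_delta()),
    dir = list(U1 = U1, U2 = U2, V1 = kernel_delta(), V2 = kernel_delta())
  )
  class(bank) <- "nsct_filter_bank"
  bank
}

#' Perfect-reconstruction residuals of a filter bank
#'
#' Evaluates `|H1*G1 + H2*G2 - 1|` and `|U1*V1 + U2*V2 - 1|` on an
#' `n x n` frequency grid and returns the maxima.
#'
#' @param bank an `nsct_filter_bank`.
#' @param n frequency grid size per axis.
#' @return named numeric vector with elements `pyramid` and `directional`.
#' @export
pr_residuals <- function(bank, n = 256L) {
  stopifnot(inherits(bank, "nsct_filter_bank"))
  p <- bank$pyr
  d <- bank$dir
  rp <- kernel_freqz(p$H1, n) * kernel_freqz(p$G1, n) +
    kernel_freqz(p$H2, n) * kernel_freqz(p$G2, n) - 1
  rd <- kernel_freqz(d$U1, n) * kernel_freqz(d$V1, n) +
    kernel_freqz(d$U2, n) * kernel_freqz(d$V2, n) - 1
  c(pyramid = max(Mod(rp)), directional = max(Mod(rd)))
}
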