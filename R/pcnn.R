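# Simplified pulse-coupled neural network (PCNN).
#
# One neuron per pixel.  The feeding input is the (static) stimulus S in
# [0, 1]; lateral linking L is the weighted sum of the neighbours' pulses
# from the previous step; the internal activity U modulates feeding by the
# linking; a neuron fires when U exceeds its dynamic threshold, which jumps
# by V_theta on every fire and decays exponentially between fires:
#
#   L[n] = W (*) Y[n-1]
#   U[n] = S * (1 + beta * L[n])
#   Y[n] = 1  where  U[n] > exp(-alpha_theta) * theta[n-1]   (strict)
#   theta[n] = exp(-alpha_theta) * theta[n-1] + V_theta * Y[n]
#
# with Y[0] = 0 and theta[0] = 0, so every neuron with S > 0 fires at n = 1.
# This is the widely used simplified model (no feeding leak, unit feeding
# gain, one linking compartment): it exposes exactly the three parameters the
# optimizer tunes -- the threshold decay rate alpha_theta, the linking
# strength beta and the threshold amplification V_theta -- plus the fixed
# linking kernel W and iteration count T.  The returned statistic is the
# cumulative per-pixel firing count over the T iterations, the standard PCNN
# activity measure for coefficient selection in fusion.

#' Default 3x3 linking kernel
#'
#' Inverse Euclidean distance to the centre pixel: 1 on the 4-neighbours,
#' `1/sqrt(2)` on the diagonals, 0 at the centre.
#'
#' @return a 3x3 numeric matrix.
#' @export
pcnn_linking_kernel <- function() {
  d <- 1 / sqrt(2)
  matrix(c(d, 1, d,
           1, 0, 1,
           d, 1, d), 3, 3, byrow = TRUE)
}

#' PCNN parameter set
#'
#' @param alpha_theta threshold decay rate, `> 0` (dimensionless; the
#'   threshold is multiplied by `exp(-alpha_theta)` each iteration).
#' @param beta linking strength, `>= 0` (0 decouples the neurons).
#' @param V_theta threshold amplification on firing, `> 0`.
#' @param iterations number of simulation steps `T >= 1`.
#' @param W linking kernel: small non-negative matrix with zero centre and at
#'   least one positive off-centre weight (odd dimensions).
#' @return an object of class `pcnn_params`.
#' @export
pcnn_params <- function(alpha_theta, beta, V_theta, iterations = 100L,
                        W = pcnn_linking_kernel()) {
  stopifnot(alpha_theta > 0, beta >= 0, V_theta > 0, iterations >= 1L)
  W <- as.matrix(W)
  ci <- (nrow(W) + 1L) %/% 2L; cj <- (ncol(W) + 1L) %/% 2L
  if (nrow(W) %% 2L != 1L || ncol(W) %% 2L != 1L) stop("W must have odd dimensions")
  if (W[ci, cj] != 0) stop("W must have a zero centre weight")
  if (any(W < 0) || all(W <= 0)) {
    stop("W must be non-negative with at least one positive off-centre weight")
  }
  structure(list(alpha_theta = alpha_theta, beta = beta, V_theta = V_theta,
                 iterations = as.integer(iterations), W = W),
            class = "pcnn_params")
}

#' Run the PCNN on a stimulus image
#'
#' Iterates the simplified neuron model above for `params$iterations` steps
#' and returns the per-pixel cumulative firing counts.  The linking
#' convolution uses symmetric (mirror) boundary extension.  The model is
#' fully deterministic.
#'
#' @param stimulus numeric matrix with values in \[0, 1\] (use
#'   [normalize_intensity()] to condition arbitrary inputs).
#' @param params a [pcnn_params()] object.
#' @return integer matrix of firing counts in `0..iterations`, same shape as
#'   the stimulus, with class `pcnn_firing_map`.
#' @export
#' @examples
#' counts <- run_pcnn(matrix(0.5, 1, 2),
#'                    pcnn_params(log(2), 0, 2, iterations = 5))
#' counts[1, 1]  # fires at n = 1 and n = 4
run_pcnn <- function(stimulus, params) {
  stopifnot(inherits(params, "pcnn_params"))
  S <- as_pixel_matrix(stimulus)
  if (!all(is.finite(S)) || min(S) < 0 || max(S) > 1) {
    stop("PCNN stimulus must lie in [0, 1]")
  }
  Wk <- kernel_from_matrix(params$W)
  decay <- exp(-params$alpha_theta)
  theta <- matrix(0, nrow(S), ncol(S))
  Y <- matrix(0, nrow(S), ncol(S))
  counts <- matrix(0L, nrow(S), ncol(S))
  for (n in seq_len(params$iterations)) {
    L <- if (params$beta > 0) conv2_sym(Y, Wk) else 0
    U <- S * (1 + params$beta * L)
    theta <- decay * theta
    Y <- (U > theta) * 1
    theta <- theta + params$V_theta * Y
    counts <- counts + Y
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("pcnn_firing_map", "matrix"))
}
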