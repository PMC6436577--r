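# Independent reference implementations used as oracles.  These are written
# as plain scalar loops, deliberately sharing no code with the package.

# Naive scalar-loop PCNN: synchronous update, mirror boundary, firing when
# the feeding*linking activity exceeds the decayed threshold (strict).
pcnn_oracle <- function(S, alpha_theta, beta, V_theta, iterations,
                        W = spectfuse::pcnn_linking_kernel()) {
  M <- nrow(S); N <- ncol(S)
  ci <- (nrow(W) + 1L) %/% 2L; cj <- (ncol(W) + 1L) %/% 2L
  reflect <- function(i, n) {
    if (i < 1L) 1L - i else if (i > n) 2L * n + 1L - i else i
  }
  theta <- matrix(0, M, N)
  Y <- matrix(0, M, N)
  counts <- matrix(0L, M, N)
  fire_times <- vector("list", M * N)
  for (n in seq_len(iterations)) {
    L <- matrix(0, M, N)
    for (i in seq_len(M)) for (j in seq_len(N)) {
      acc <- 0
      for (wi in seq_len(nrow(W))) for (wj in seq_len(ncol(W))) {
        if (W[wi, wj] != 0) {
          acc <- acc + W[wi, wj] *
            Y[reflect(i + wi - ci, M), reflect(j + wj - cj, N)]
        }
      }
      L[i, j] <- acc
    }
    U <- S * (1 + beta * L)
    theta <- exp(-alpha_theta) * theta
    Ynew <- matrix(0, M, N)
    for (i in seq_len(M)) for (j in seq_len(N)) {
      if (U[i, j] > theta[i, j]) {
        Ynew[i, j] <- 1
        fire_times[[(j - 1L) * M + i]] <-
          c(fire_times[[(j - 1L) * M + i]], n)
      }
    }
    theta <- theta + V_theta * Ynew
    Y <- Ynew
    counts <- counts + Ynew
  }
  list(counts = counts, fire_times = fire_times)
}

# Direct-formula metric oracles (explicit loops over the definitions).
sd_oracle <- function(x) {
  m <- mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / length(x))
}

mean_gradient_oracle <- function(x) {
  M <- nrow(x); N <- ncol(x)
  s <- 0
  for (i in seq_len(M - 1)) for (j in seq_len(N - 1)) {
    dx <- x[i + 1, j] - x[i, j]
    dy <- x[i, j + 1] - x[i, j]
    s <- s + sqrt((dx^2 + dy^2) / 2)
  }
  s / ((M - 1) * (N - 1))
}

sf_oracle <- function(x) {
  M <- nrow(x); N <- ncol(x)
  rf <- 0; cf <- 0
  for (i in seq_len(M)) for (j in 2:N) rf <- rf + (x[i, j] - x[i, j - 1])^2
  for (i in 2:M) for (j in seq_len(N)) cf <- cf + (x[i, j] - x[i - 1, j])^2
  rf <- sqrt(rf / (M * N)); cf <- sqrt(cf / (M * N))
  c(sf = sqrt(rf^2 + cf^2), rf = rf, cf = cf)
}

entropy_oracle <- function(q, levels = 256) {
  E <- 0
  for (l in 0:(levels - 1)) {
    p <- sum(q == l) / length(q)
    if (p > 0) E <- E - p * log2(p)
  }
  E
}

# Small random test images.
random_gray <- function(n = 16, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

random_color_unit <- function(n = 16, seed = 1) {
  set.seed(seed)
  color_image(array(runif(n * n * 3), c(n, n, 3)), range = "unit")
}

as_mat <- function(img) spectfuse:::as_pixel_matrix(img)

small_fusion_config <- function(seed = 5, ...) {
  fusion_config(nsct_levels = 2, nsct_dirs = c(1, 1), pcnn_iterations = 20,
                sfla_pop = 6, sfla_memeplexes = 2, sfla_steps = 2,
                sfla_shuffles = 2, seed = seed, ...)
}
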