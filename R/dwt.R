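# Compact orthonormal Haar 2-D DWT, used only by the `dwt` fusion baseline.
# Exactly invertible; odd dimensions are handled by edge replication before
# the transform and cropping after the inverse.

haar_step <- function(x) {
  M <- nrow(x); N <- ncol(x)
  stopifnot(M %% 2L == 0L, N %% 2L == 0L)
  s2 <- sqrt(2)
  rl <- (x[seq(1L, M, 2L), , drop = FALSE] + x[seq(2L, M, 2L), , drop = FALSE]) / s2
  rh <- (x[seq(1L, M, 2L), , drop = FALSE] - x[seq(2L, M, 2L), , drop = FALSE]) / s2
  list(
    ll = (rl[, seq(1L, N, 2L), drop = FALSE] + rl[, seq(2L, N, 2L), drop = FALSE]) / s2,
    lh = (rl[, seq(1L, N, 2L), drop = FALSE] - rl[, seq(2L, N, 2L), drop = FALSE]) / s2,
    hl = (rh[, seq(1L, N, 2L), drop = FALSE] + rh[, seq(2L, N, 2L), drop = FALSE]) / s2,
    hh = (rh[, seq(1L, N, 2L), drop = FALSE] - rh[, seq(2L, N, 2L), drop = FALSE]) / s2
  )
}

haar_istep <- function(b) {
  s2 <- sqrt(2)
  rl <- matrix(0, nrow(b$ll), 2L * ncol(b$ll))
  rh <- rl
  rl[, seq(1L, ncol(rl), 2L)] <- (b$ll + b$lh) / s2
  rl[, seq(2L, ncol(rl), 2L)] <- (b$ll - b$lh) / s2
  rh[, seq(1L, ncol(rh), 2L)] <- (b$hl + b$hh) / s2
  rh[, seq(2L, ncol(rh), 2L)] <- (b$hl - b$hh) / s2
  x <- matrix(0, 2L * nrow(rl), ncol(rl))
  x[seq(1L, nrow(x), 2L), ] <- (rl + rh) / s2
  x[seq(2L, nrow(x), 2L), ] <- (rl - rh) / s2
  x
}

pad_even <- function(x) {
  if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), ])
  if (ncol(x) %% 2L == 1L) x <- cbind(x, x[, ncol(x)])
  x
}

haar_dwt2 <- function(x, levels = 2L) {
  dims <- vector("list", levels)
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    dims[[l]] <- dim(x)
    x <- pad_even(x)
    b <- haar_step(x)
    details[[l]] <- b[c("lh", "hl", "hh")]
    x <- b$ll
  }
  list(approx = x, details = details, dims = dims, levels = levels)
}

haar_idwt2 <- function(dec) {
  x <- dec$approx
  for (l in rev(seq_len(dec$levels))) {
    d <- dec$details[[l]]
    x <- haar_istep(list(ll = x, lh = d$lh, hl = d$hl, hh = d$hh))
    x <- x[seq_len(dec$dims[[l]][1L]), seq_len(dec$dims[[l]][2L]), drop = FALSE]
  }
  x
}

# Max-|coefficient| detail / averaged approximation wavelet fusion of two
# equally sized matrices (the classical DWT fusion baseline rule).
fuse_dwt_maxavg <- function(a, b, levels = 2L) {
  da <- haar_dwt2(a, levels)
  db <- haar_dwt2(b, levels)
  fused <- da
  fused$approx <- (da$approx + db$approx) / 2
  for (l in seq_len(levels)) {
    for (nm in c("lh", "hl", "hh")) {
      ca <- da$details[[l]][[nm]]
      cb <- db$details[[l]][[nm]]
      fused$details[[l]][[nm]] <- ifelse(abs(ca) >= abs(cb), ca, cb)
    }
  }
  haar_idwt2(fused)
}
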