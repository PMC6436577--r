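bank <- build_filter_bank()

test_that("filter bank satisfies both perfect-reconstruction identities", {
  res <- pr_residuals(bank, n = 256L)
  expect_lt(res["pyramid"], 1e-8)
  expect_lt(res["directional"], 1e-8)
  # highpass kills DC (forced by PR and H1(0,0) = 1)
  expect_lt(abs(sum(bank$pyr$H2$weights)), 1e-8)
  expect_error(build_filter_bank("nosuch"), "supported")
})

test_that("decomposition yields 2^n directional bands per level at full size", {
  x <- matrix(rnorm(32 * 32), 32)
  p <- nsct_decompose(x, list(levels = 2, dirs = c(2, 3)), bank)
  expect_length(p$levels[[1]], 4L)
  expect_length(p$levels[[2]], 8L)
  for (b in unlist(p$levels, recursive = FALSE)) {
    expect_identical(dim(b), dim(x))
  }
  expect_identical(dim(p$low), dim(x))
})

test_that("a constant image has a constant low band and zero directional bands", {
  p <- nsct_decompose(matrix(4.2, 32, 32), list(levels = 2, dirs = c(1, 2)), bank)
  expect_lt(max(abs(p$low - 4.2)), 1e-8)
  for (b in unlist(p$levels, recursive = FALSE)) {
    expect_lt(max(abs(b)), 1e-8)
  }
})

test_that("round trip is exact within 1e-6 across decomposition specs", {
  set.seed(11)
  specs <- list(list(levels = 1, dirs = 1),
                list(levels = 2, dirs = c(2, 3)),
                list(levels = 3, dirs = c(2, 2, 3)))
  for (sp in specs) {
    x <- matrix(runif(64 * 64), 64)
    y <- nsct_reconstruct(nsct_decompose(x, sp, bank), bank)
    expect_lt(max(abs(y - x)), 1e-6)
  }
})

test_that("the transform is linear", {
  set.seed(12)
  x1 <- matrix(runif(32 * 32), 32)
  x2 <- matrix(runif(32 * 32), 32)
  sp <- list(levels = 2, dirs = c(1, 2))
  p1 <- nsct_decompose(x1, sp, bank)
  p2 <- nsct_decompose(x2, sp, bank)
  comb <- p1
  comb$low <- 2 * p1$low - 3 * p2$low
  for (j in seq_along(comb$levels)) {
    for (d in seq_along(comb$levels[[j]])) {
      comb$levels[[j]][[d]] <- 2 * p1$levels[[j]][[d]] - 3 * p2$levels[[j]][[d]]
    }
  }
  expect_lt(max(abs(nsct_reconstruct(comb, bank) - (2 * x1 - 3 * x2))), 1e-6)
})

test_that("bands commute with translation away from the boundary", {
  set.seed(13)
  x <- matrix(runif(64 * 64), 64)
  sh <- function(m) m[c(4:64, 1:3), c(7:64, 1:6)]
  sp <- list(levels = 2, dirs = c(1, 2))
  p1 <- nsct_decompose(x, sp, bank)
  p2 <- nsct_decompose(sh(x), sp, bank)
  interior <- 17:48
  for (j in seq_along(p1$levels)) {
    for (d in seq_along(p1$levels[[j]])) {
      err <- max(abs(sh(p1$levels[[j]][[d]]) -
                       p2$levels[[j]][[d]])[interior, interior])
      expect_lt(err, 1e-6)
    }
  }
})

test_that("a pure sinusoid concentrates energy in its directional wedge", {
  ii <- row(matrix(0, 64, 64))
  x <- sin(2 * pi * 0.35 * ii)   # oscillates along rows
  p <- nsct_decompose(x, list(levels = 1, dirs = 3), bank)
  en <- vapply(p$levels[[1]], function(b) sum(b^2), numeric(1))
  # the first half of the tree descends from the fan passing high row
  # frequencies, where this sinusoid lives
  expect_gt(sum(en[1:4]) / sum(en), 0.8)
})

test_that("invalid specs and malformed pyramids are rejected", {
  x <- matrix(0.5, 16, 16)
  expect_error(nsct_decompose(x, list(levels = 5, dirs = rep(1, 5)), bank),
               "too deep")
  expect_error(nsct_decompose(x, list(levels = 2, dirs = 1), bank), "invalid")
  p <- nsct_decompose(x, list(levels = 1, dirs = 1), bank)
  p$levels[[1]][[1]] <- matrix(0, 8, 8)
  expect_error(nsct_reconstruct(p, bank), "shape mismatch")
  p2 <- nsct_decompose(x, list(levels = 1, dirs = 1), bank)
  p2$levels[[1]][[2]] <- NULL
  expect_error(nsct_reconstruct(p2, bank), "expected")
})
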