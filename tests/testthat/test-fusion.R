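p_fast <- function(beta = 0) pcnn_params(0.5, beta, 10, iterations = 10)

test_that("band activity is sign-invariant and tracks coefficient magnitude", {
  expect_true(all(pcnn_activity(matrix(0, 4, 4), p_fast()) == 0L))
  set.seed(61)
  band <- matrix(rnorm(16), 4)
  expect_identical(pcnn_activity(band, p_fast(0.3)),
                   pcnn_activity(-band, p_fast(0.3)))
  band2 <- matrix(0.1, 4, 4)
  band2[2, 3] <- -5   # dominant |coefficient|
  counts <- pcnn_activity(band2, p_fast())
  expect_true(all(counts[2, 3] >= counts))
})

test_that("band fusion selects by firing count with mean tie-break", {
  set.seed(62)
  a <- matrix(rnorm(64), 8)
  expect_identical(fuse_bands_pcnn(a, a, p_fast(0.2)), a)
  # dominant coefficients in A fire more (decoupled), so A is selected there
  a <- matrix(0.1, 4, 4); b <- matrix(0.1, 4, 4)
  a[1, 1] <- 3; b[4, 4] <- -2
  fused <- fuse_bands_pcnn(a, b, p_fast())
  expect_equal(fused[1, 1], 3)
  expect_equal(fused[4, 4], -2)
  ca <- pcnn_activity(a, p_fast()); cb <- pcnn_activity(b, p_fast())
  ties <- ca == cb
  expect_equal(fused[ties], ((a + b) / 2)[ties])
  first <- fuse_bands_pcnn(a, b, p_fast(), tie_policy = "first")
  expect_equal(first[ties], a[ties])
  expect_error(fuse_bands_pcnn(a, matrix(0, 3, 3), p_fast()), "shapes differ")
})

test_that("a 2x2 fusion matches a hand trace through the scalar oracle", {
  a <- matrix(c(0.9, 0.1, 0.4, 0.2), 2)
  b <- matrix(c(0.2, 0.8, 0.1, 0.6), 2)
  p <- pcnn_params(log(2), 0, 2, iterations = 5)
  sa <- normalize_intensity(abs(a))$pixels
  sb <- normalize_intensity(abs(b))$pixels
  ca <- pcnn_oracle(sa, log(2), 0, 2, 5)$counts
  cb <- pcnn_oracle(sb, log(2), 0, 2, 5)$counts
  expected <- (ca > cb) * a + (cb > ca) * b + (ca == cb) * (a + b) / 2
  expect_equal(fuse_bands_pcnn(a, b, p), expected)
})

test_that("band fitness is entropy of the fused band and ranks structure", {
  cst <- matrix(5, 8, 8)
  expect_equal(band_fitness(p_fast(), cst, cst), 0)
  # identical two-level bands fuse to themselves: entropy 1 bit > 0
  two <- matrix(rep(c(0, 1), each = 32), 8)
  expect_equal(band_fitness(p_fast(), two, two), 1)
  set.seed(63)
  a <- matrix(rnorm(64), 8); b <- matrix(rnorm(64), 8)
  expect_identical(band_fitness(p_fast(0.4), a, b),
                   band_fitness(p_fast(0.4), a, b))
  expect_gt(band_fitness(p_fast(), a, b, fitness_name = "gradient"), 0)
  expect_gt(band_fitness(p_fast(), a, b, fitness_name = "entropy_gradient"), 0)
  expect_error(band_fitness(p_fast(), a, b, fitness_name = "nope"), "unknown")
})

test_that("pyramid fusion is an identity on equal pyramids and stays in bounds", {
  set.seed(64)
  x <- matrix(runif(32 * 32), 32)
  cfg <- small_fusion_config()
  pyr <- nsct_decompose(x, cfg$nsct_spec)
  fp <- fuse_pyramids(pyr, pyr, cfg)
  expect_equal(fp$pyramid$low, pyr$low)
  for (j in seq_along(pyr$levels)) {
    for (d in seq_along(pyr$levels[[j]])) {
      expect_equal(fp$pyramid$levels[[j]][[d]], pyr$levels[[j]][[d]])
    }
  }
  for (sel in fp$params) {
    pos <- c(sel$alpha_theta, sel$beta, sel$V_theta)
    expect_true(all(pos >= cfg$bounds[1, ] & pos <= cfg$bounds[2, ]))
    # optimizer dominance over its own initial population
    expect_gte(sel$fitness, sel$initial_best_fitness)
  }
})

test_that("regional average-energy low rule picks the stronger neighbourhood", {
  a <- matrix(0, 8, 8); b <- matrix(0, 8, 8)
  a[2:4, 2:4] <- 4      # energetic patch in A
  b[6:8, 6:8] <- 3      # weaker patch in B elsewhere
  fused <- spectfuse:::fuse_bands_energy(a, b)
  expect_equal(fused[3, 3], 4)
  expect_equal(fused[7, 7], 3)
  expect_identical(spectfuse:::fuse_bands_energy(a, a), a)
})

test_that("end-to-end self-fusion returns the shared intensity", {
  spec <- phantom_spec(size = c(64, 64), seed = 65)
  ct <- make_ct_phantom(spec)
  g <- as_mat(ct) / 255
  spect <- color_image(array(rep(g, 3) * 255, c(64, 64, 3)), range = "8bit")
  cfg <- small_fusion_config()
  res <- fuse_spect_ct(spect, ct, cfg)
  expect_lt(max(abs(as_mat(res$intensity) - g)), 1e-5)
  expect_s3_class(res$metrics, "metrics_report")
  expect_identical(dim(unclass(res$fused)), c(64L, 64L, 3L))
})

test_that("hue and saturation pass through the pipeline unchanged", {
  pair <- make_phantom_pair(phantom_spec(size = c(64, 64), seed = 66))
  cfg <- small_fusion_config()
  ihs <- rgb_to_ihs(spectfuse:::to_unit(pair$spect))
  res <- fuse_spect_ct(pair$spect, pair$ct, cfg)
  # invert/forward with the fused intensity: H and S are exactly carried
  out <- ihs_to_rgb(as_mat(res$intensity), ihs$H, ihs$S, clip = FALSE)
  t2 <- rgb_to_ihs(out)
  expect_lt(max(abs(t2$S - ihs$S)), 1e-9)
  # hue is well defined only away from the gray axis: at S ~ 0 the angle of
  # a roundoff-sized chroma vector is arbitrary
  chroma <- ihs$S > 1e-8
  expect_lt(max(abs((t2$H - ihs$H)[chroma])), 1e-9)
})

test_that("fusion is deterministic given the configuration seed", {
  pair <- make_phantom_pair(phantom_spec(size = c(32, 32), seed = 67))
  cfg <- small_fusion_config(seed = 9)
  r1 <- fuse_spect_ct(pair$spect, pair$ct, cfg)
  r2 <- fuse_spect_ct(pair$spect, pair$ct, cfg)
  expect_identical(unclass(r1$fused), unclass(r2$fused))
  expect_identical(r1$chosen_params, r2$chosen_params)
})

test_that("IHS baseline with CT equal to the intensity returns the SPECT image", {
  img <- random_color_unit(16, seed = 68)
  I <- rgb_to_ihs(img)$I
  res <- baseline_fuse(img, raster_image(I, range = "unit"), "ihs",
                       small_fusion_config())
  expect_lt(max(abs(unclass(res$fused) / 255 - unclass(img))), 1e-9)
})

test_that("NSCT max/average baseline follows its stated rule", {
  pair <- make_phantom_pair(phantom_spec(size = c(32, 32), seed = 69))
  cfg <- small_fusion_config()
  # identity on identical inputs
  g <- as_mat(pair$ct) / 255
  spect_g <- color_image(array(rep(g, 3) * 255, c(32, 32, 3)), range = "8bit")
  res <- baseline_fuse(spect_g, pair$ct, "nsct_fl", cfg)
  expect_lt(max(abs(as_mat(res$intensity) - g)), 1e-5)
  # low band is the average of the two input low bands
  I <- rgb_to_ihs(spectfuse:::to_unit(pair$spect))$I
  pa <- nsct_decompose(I, cfg$nsct_spec)
  pb <- nsct_decompose(g, cfg$nsct_spec)
  fused_low <- (pa$low + pb$low) / 2
  # reconstruct a pyramid holding only the low band to isolate it
  iso <- function(p) {
    for (j in seq_along(p$levels)) {
      for (d in seq_along(p$levels[[j]])) p$levels[[j]][[d]][] <- 0
    }
    nsct_reconstruct(p)
  }
  resl <- baseline_fuse(pair$spect, pair$ct, "nsct_fl", cfg)
  # directional max rule: recompute independently
  fused2 <- pa
  fused2$low <- fused_low
  for (j in seq_along(pa$levels)) {
    for (d in seq_along(pa$levels[[j]])) {
      A <- pa$levels[[j]][[d]]; B <- pb$levels[[j]][[d]]
      fused2$levels[[j]][[d]] <- ifelse(abs(A) >= abs(B), A, B)
    }
  }
  expect_equal(as_mat(resl$intensity),
               spectfuse:::clamp(nsct_reconstruct(fused2), 0, 1))
})

test_that("DWT baseline is exactly invertible and an identity on equal inputs", {
  set.seed(70)
  x <- matrix(runif(48 * 40), 48)
  dec <- spectfuse:::haar_dwt2(x, 2)
  expect_lt(max(abs(spectfuse:::haar_idwt2(dec) - x)), 1e-12)
  expect_lt(max(abs(spectfuse:::fuse_dwt_maxavg(x, x) - x)), 1e-12)
  # odd sizes are padded and cropped transparently
  y <- matrix(runif(33 * 37), 33)
  expect_lt(max(abs(spectfuse:::haar_idwt2(spectfuse:::haar_dwt2(y, 2)) - y)),
            1e-12)
})

test_that("unknown baseline methods are rejected", {
  pair <- make_phantom_pair(phantom_spec(size = c(32, 32), seed = 71))
  expect_error(baseline_fuse(pair$spect, pair$ct, "magic"), "arg")
})
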