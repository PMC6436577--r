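sphere <- function(x) -sum(x^2)
box3 <- rbind(rep(-5, 3), rep(5, 3))

test_that("population initialization is seeded, in-bounds and sorted", {
  cfg <- sfla_config(pop_size = 12, memeplexes = 3, bounds = box3, seed = 31)
  p1 <- initialize_population(cfg, sphere)
  p2 <- initialize_population(cfg, sphere)
  expect_identical(p1, p2)
  expect_true(all(p1$positions >= -5 & p1$positions <= 5))
  expect_true(all(diff(p1$fitness) <= 0))
  expect_error(initialize_population(cfg, function(x) NaN), "non-finite")
})

test_that("memeplex partition deals frogs round-robin by rank", {
  pop <- list(positions = matrix(1:18, 6, 3), fitness = c(9, 8, 7, 6, 5, 4))
  gs <- partition_memeplexes(pop, 2)
  expect_equal(gs[[1]]$fitness, c(9, 7, 5))
  expect_equal(gs[[2]]$fitness, c(8, 6, 4))
  expect_equal(gs[[1]]$positions[1, ], pop$positions[1, ])
  one <- partition_memeplexes(pop, 1)
  expect_identical(one[[1]], pop)
  expect_error(partition_memeplexes(pop, 4), "not divisible")
  # each memeplex's best is among the top m frogs overall
  for (m in c(2, 3)) {
    gs <- partition_memeplexes(pop, m)
    bests <- vapply(gs, function(g) g$fitness[1], numeric(1))
    expect_true(all(bests %in% pop$fitness[seq_len(m)]))
  }
})

test_that("the leap follows the update rule and respects the S_max clamp", {
  step <- spectfuse:::leap_step(c(1, 2, -1), c(0, 0, 0), 0.5, rep(10, 3))
  expect_equal(step, c(0.5, 1, -0.5))
  step <- spectfuse:::leap_step(c(100, 0, 0), c(0, 0, 0), 1, rep(1, 3))
  expect_equal(step, c(1, 0, 0))
  step <- spectfuse:::leap_step(c(-100, 0, 0), c(0, 0, 0), 1, rep(1, 3))
  expect_equal(step, c(-1, 0, 0))
})

test_that("the replacement cascade falls back to a random in-bounds frog", {
  # Positions score by lookup; any move lands on an unknown position and
  # scores -Inf ... use a large negative instead to keep fitness finite.
  known <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, 3, byrow = TRUE)
  fit <- function(x) {
    hit <- apply(known, 1, function(k) all(abs(k - x) < 1e-12))
    if (any(hit)) c(10, 5, 1)[which(hit)] else -1e6
  }
  group <- list(positions = known, fitness = c(10, 5, 1))
  cfg <- sfla_config(pop_size = 3, memeplexes = 1, bounds = box3, seed = 32)
  set.seed(33)
  upd <- local_search_step(group, known[1, ], cfg, fit)
  # the worst frog was replaced by a random frog scoring -1e6
  expect_true(min(upd$group$fitness) == -1e6)
  worst <- upd$group$positions[3, ]
  expect_true(all(worst >= -5 & worst <= 5))
  expect_false(any(apply(known, 1, function(k) all(k == worst))))
  expect_lte(upd$evals, 3L)
})

test_that("optimizer solves the sphere and tracks a monotone best", {
  cfg <- sfla_config(pop_size = 30, memeplexes = 3, local_steps = 20,
                     shuffles = 20, bounds = box3, seed = 41)
  res <- sfla_optimize(sphere, cfg)
  expect_gt(res$best$fitness, -1e-2)
  expect_true(all(diff(res$history) >= 0))
  expect_true(all(res$best$position >= -5 & res$best$position <= 5))
})

test_that("optimization is deterministic for a fixed seed", {
  cfg <- sfla_config(pop_size = 12, memeplexes = 2, local_steps = 5,
                     shuffles = 4, bounds = box3, seed = 42)
  r1 <- sfla_optimize(sphere, cfg)
  r2 <- sfla_optimize(sphere, cfg)
  expect_identical(r1, r2)
})

test_that("evaluation count stays within the cascade budget", {
  cfg <- sfla_config(pop_size = 12, memeplexes = 3, local_steps = 6,
                     shuffles = 5, bounds = box3, seed = 43)
  res <- sfla_optimize(sphere, cfg)
  # per leap at most 3 evaluations (candidate, global-best retry, random
  # replacement), plus the initial population scoring
  expect_lte(res$evals, 12 + 5 * 3 * 6 * 3)
  expect_gte(res$evals, 12 + 5 * 3 * 6)
})

test_that("a single memeplex degenerates to plain local search and still works", {
  cfg <- sfla_config(pop_size = 10, memeplexes = 1, local_steps = 15,
                     shuffles = 10, bounds = box3, seed = 44)
  res <- sfla_optimize(sphere, cfg)
  expect_true(all(diff(res$history) >= 0))
  expect_gt(res$best$fitness, -1)
})

test_that("injected positions enter the initial population", {
  cfg <- sfla_config(pop_size = 6, memeplexes = 2, bounds = box3, seed = 45)
  inj <- matrix(c(0.1, 0.1, 0.1), 1)
  pop <- initialize_population(cfg, sphere, inject = inj)
  hit <- apply(pop$positions, 1, function(r) all(abs(r - 0.1) < 1e-12))
  expect_true(any(hit))
  # injected near-optimum dominates random frogs in the box
  expect_equal(unname(pop$positions[1, ]), c(0.1, 0.1, 0.1))
})

test_that("configuration invariants are enforced", {
  expect_error(sfla_config(pop_size = 10, memeplexes = 3, bounds = box3),
               "divisible")
  expect_error(sfla_config(bounds = rbind(c(0, 0), c(1, -1))), "bounds")
  expect_error(sfla_config(bounds = box3, s_max = -1), "s_max")
})
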