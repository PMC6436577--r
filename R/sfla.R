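# Shuffled frog-leaping algorithm (SFLA).
#
# A memetic population search over a box domain Omega.  Fitness is maximized.
# Each round ("shuffle"): the descending-sorted population is dealt
# round-robin into m memeplexes; within each memeplex the worst frog P_w
# repeatedly tries to leap toward the memeplex best P_b,
#
#     S_j    = rand() * (P_b - P_w),   clamped per coordinate to [-S_max, S_max]
#     P_w,new = P_w + S_j
#
# accepting the candidate only if it stays in Omega and strictly improves
# F(P_w).  On failure the same leap is retried toward the global best P_g;
# if that also fails, P_w is replaced by a fresh uniform random frog in
# Omega (the classical replacement cascade).  After the local steps the
# memeplexes are merged, re-sorted, and re-dealt.
#
# The optimizer is generic over the fitness function; the fusion pipeline
# uses it on the 3-D PCNN parameter space (alpha_theta, beta, V_theta).

#' SFLA configuration
#'
#' @param pop_size total number of frogs `F` (must equal
#'   `memeplexes * frogs_per_memeplex`).
#' @param memeplexes number of sub-populations `m`.
#' @param local_steps leap attempts per memeplex per shuffle round `N`.
#' @param shuffles number of global shuffle rounds.
#' @param bounds 2 x d numeric matrix: row 1 lower, row 2 upper bound per
#'   coordinate of the search box Omega.
#' @param s_max per-coordinate maximum leap magnitude (recycled to d);
#'   default half the box width.
#' @param seed integer RNG seed; the whole optimization is deterministic
#'   given the seed.
#' @param per_coordinate_rand draw one `rand()` per coordinate of the leap
#'   (default) instead of a single scalar applied to all coordinates.  With a
#'   scalar draw every candidate lies on the line segment between the worst
#'   and the best frog, so a converging population collapses onto a line and
#'   late-stage refinement stalls; the per-coordinate draw explores the
#'   axis-aligned box spanned by the two frogs and avoids that degeneracy.
#'   Set to `FALSE` for the literal scalar-rand update.
#' @return an object of class `sfla_config`.
#' @export
sfla_config <- function(pop_size = 30L, memeplexes = 3L, local_steps = 10L,
                        shuffles = 10L, bounds, s_max = NULL, seed = 1L,
                        per_coordinate_rand = TRUE) {
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2L, all(bounds[2L, ] > bounds[1L, ]))
  d <- ncol(bounds)
  if (is.null(s_max)) s_max <- (bounds[2L, ] - bounds[1L, ]) / 2
  s_max <- rep_len(as.numeric(s_max), d)
  stopifnot(all(s_max > 0), pop_size >= 1L, memeplexes >= 1L,
            local_steps >= 1L, shuffles >= 1L)
  if (pop_size %% memeplexes != 0L) {
    stop("pop_size (", pop_size, ") must be divisible by memeplexes (",
         memeplexes, ")")
  }
  structure(list(pop_size = as.integer(pop_size),
                 memeplexes = as.integer(memeplexes),
                 local_steps = as.integer(local_steps),
                 shuffles = as.integer(shuffles),
                 bounds = bounds, s_max = s_max, seed = as.integer(seed),
                 per_coordinate_rand = isTRUE(per_coordinate_rand)),
            class = "sfla_config")
}

in_bounds <- function(x, bounds) {
  all(x >= bounds[1L, ]) && all(x <= bounds[2L, ])
}

score_position <- function(fitness, x) {
  f <- fitness(x)
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
    stop("fitness returned a non-finite value at position (",
         paste(signif(x, 6), collapse = ", "), ")")
  }
  f
}

sort_population <- function(pop) {
  o <- order(pop$fitness, decreasing = TRUE)
  list(positions = pop$positions[o, , drop = FALSE], fitness = pop$fitness[o])
}

#' Initialize and score an SFLA population
#'
#' Samples `pop_size` frogs uniformly in the box, scores them and sorts by
#' descending fitness.  Seeds the RNG from `cfg$seed`, so two calls with the
#' same configuration return identical populations.
#'
#' @param cfg an [sfla_config()].
#' @param fitness function mapping a length-d numeric position to a finite
#'   scalar score (larger is better).
#' @param inject optional matrix of positions (one per row) forced into the
#'   initial population, replacing the last sampled frogs; used to seed the
#'   search with known-good parameter sets.
#' @return list with `positions` (F x d matrix, best first) and `fitness`.
#' @export
initialize_population <- function(cfg, fitness, inject = NULL) {
  stopifnot(inherits(cfg, "sfla_config"))
  d <- ncol(cfg$bounds)
  with_seed(cfg$seed, {
    pos <- matrix(runif(cfg$pop_size * d), cfg$pop_size, d)
    pos <- sweep(pos, 2L, cfg$bounds[2L, ] - cfg$bounds[1L, ], `*`)
    pos <- sweep(pos, 2L, cfg$bounds[1L, ], `+`)
    if (!is.null(inject)) {
      inject <- matrix(inject, ncol = d)
      stopifnot(nrow(inject) <= cfg$pop_size)
      rows <- cfg$pop_size - nrow(inject) + seq_len(nrow(inject))
      pos[rows, ] <- inject
    }
    fit <- apply(pos, 1L, function(x) score_position(fitness, x))
    sort_population(list(positions = pos, fitness = fit))
  })
}

#' Deal a sorted population into memeplexes
#'
#' Round-robin deal: the frog ranked `k` (0-based) goes to memeplex
#' `k mod m`, spreading quality evenly across memeplexes.
#'
#' @param population sorted population from [initialize_population()].
#' @param m number of memeplexes; must divide the population size.
#' @return list of `m` populations.
#' @export
partition_memeplexes <- function(population, m) {
  F_ <- nrow(population$positions)
  if (F_ %% m != 0L) stop("population size ", F_, " not divisible by m = ", m)
  lapply(seq_len(m), function(g) {
    idx <- seq(g, F_, by = m)
    list(positions = population$positions[idx, , drop = FALSE],
         fitness = population$fitness[idx])
  })
}

# The leap increment: rand * (from - to_worst), clamped to +/- s_max.
leap_step <- function(p_target, p_w, r, s_max) {
  clamp(r * (p_target - p_w), -s_max, s_max)
}

#' One local-search step on a memeplex
#'
#' Applies the leap/retry/randomize cascade to the memeplex's worst frog and
#' re-sorts.  Consumes RNG state; callers seed once per optimization.
#'
#' @param group memeplex (list with `positions`, `fitness`, sorted
#'   descending).
#' @param p_g global best position.
#' @param cfg an [sfla_config()].
#' @param fitness fitness function.
#' @return list with the updated `group` and `evals`, the number of fitness
#'   evaluations spent (1 to 3).
#' @export
local_search_step <- function(group, p_g, cfg, fitness) {
  n <- nrow(group$positions)
  p_b <- group$positions[1L, ]
  p_w <- group$positions[n, ]
  f_w <- group$fitness[n]
  d <- length(p_w)
  evals <- 0L
  draw <- function() if (cfg$per_coordinate_rand) runif(d) else runif(1L)

  try_candidate <- function(p_target) {
    cand <- p_w + leap_step(p_target, p_w, draw(), cfg$s_max)
    if (!in_bounds(cand, cfg$bounds)) return(NULL)
    evals <<- evals + 1L
    f <- score_position(fitness, cand)
    if (f > f_w) list(position = cand, fitness = f) else NULL
  }

  res <- try_candidate(p_b)
  if (is.null(res)) res <- try_candidate(p_g)
  if (is.null(res)) {
    cand <- cfg$bounds[1L, ] + runif(d) * (cfg$bounds[2L, ] - cfg$bounds[1L, ])
    evals <- evals + 1L
    res <- list(position = cand, fitness = score_position(fitness, cand))
  }
  group$positions[n, ] <- res$position
  group$fitness[n] <- res$fitness
  list(group = sort_population(group), evals = evals)
}

#' Run the shuffled frog-leaping optimizer
#'
#' @inheritParams initialize_population
#' @return list with `best` (list `position`, `fitness`: best frog ever
#'   evaluated), `history` (best-ever fitness after each shuffle round,
#'   monotone non-decreasing), `evals` (total fitness evaluations) and
#'   `initial_population`.
#' @export
#' @examples
#' cfg <- sfla_config(pop_size = 12, memeplexes = 3, local_steps = 5,
#'                    shuffles = 5, bounds = rbind(rep(-5, 3), rep(5, 3)),
#'                    seed = 7)
#' sfla_optimize(function(x) -sum(x^2), cfg)$best$fitness
sfla_optimize <- function(fitness, cfg, inject = NULL) {
  stopifnot(inherits(cfg, "sfla_config"))
  evals <- 0L
  counted <- function(x) { evals <<- evals + 1L; fitness(x) }
  pop <- initialize_population(cfg, counted, inject = inject)
  init_pop <- pop
  best <- list(position = pop$positions[1L, ], fitness = pop$fitness[1L])
  history <- numeric(cfg$shuffles)
  with_seed(cfg$seed + 1L, {
    for (round in seq_len(cfg$shuffles)) {
      groups <- partition_memeplexes(pop, cfg$memeplexes)
      for (g in seq_along(groups)) {
        for (step in seq_len(cfg$local_steps)) {
          upd <- local_search_step(groups[[g]], best$position, cfg, counted)
          groups[[g]] <- upd$group
          if (groups[[g]]$fitness[1L] > best$fitness) {
            best <- list(position = groups[[g]]$positions[1L, ],
                         fitness = groups[[g]]$fitness[1L])
          }
        }
      }
      pop <- sort_population(list(
        positions = do.call(rbind, lapply(groups, `[[`, "positions")),
        fitness = unlist(lapply(groups, `[[`, "fitness"))
      ))
      history[round] <- best$fitness
    }
  })
  list(best = best, history = history, evals = evals,
       initial_population = init_pop)
}
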