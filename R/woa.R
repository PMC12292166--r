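# Whale Optimization Algorithm over box-bounded real vectors, minimizing a
# user-supplied objective, plus its chaotic (CWOA) and dynamic chaotic
# (DCWOA) variants. The dynamic variant toggles between two chaotic maps
# when the best fitness stagnates.
#
# Randomness model (fixed, and relied upon by the reproducibility contract):
# per agent and iteration the draws are consumed in the order
#   r_scalar (branch test), p, l, r_vec (position arithmetic),
#   rand_index (only when the exploration branch fires).
# In the chaotic variants the chaotic stream replaces the r draws (one
# shared chaotic value per iteration, used for the branch scalar and
# broadcast across dimensions); p, l and the random-agent index stay
# RNG-driven.

#' Optimizer configuration
#'
#' Validates and assembles the configuration for [woa_run()].
#'
#' @param variant One of `"woa"`, `"cwoa"`, `"dcwoa"`.
#' @param dimension Number of search dimensions.
#' @param bounds Two-column matrix (or list of `c(low, high)` pairs), one row
#'   per dimension, with `low < high`.
#' @param population_size Number of whales (default 10).
#' @param max_iters Iteration budget (default 20).
#' @param spiral_b Logarithmic-spiral shape constant (default 1).
#' @param stagnation_threshold Consecutive stagnant iterations tolerated
#'   before a map switch; the switch fires when the counter exceeds it
#'   (default 5, i.e. on the 6th stagnant iteration). DCWOA only.
#' @param seed Integer seed; every random draw of the run flows from it.
#' @param map_spec Initial chaotic map, a [chaotic_map_spec()] (cwoa/dcwoa).
#' @param switch_mode `"toggle"` alternates logistic and sine on every
#'   switch; `"one_way"` only ever moves logistic to sine.
#' @param chaotic_x0 Optional chaotic seed in `(0, 1)`; drawn from the run
#'   RNG when `NULL`.
#' @param init_population Optional matrix of starting positions (rows =
#'   agents). Fewer rows than `population_size` are topped up with uniform
#'   draws within bounds; used e.g. to seed simplex corners in ensemble
#'   weight optimization.
#' @return An object of class `woa_config`.
#' @export
woa_config <- function(variant = c("woa", "cwoa", "dcwoa"),
                       dimension,
                       bounds,
                       population_size = 10L,
                       max_iters = 20L,
                       spiral_b = 1.0,
                       stagnation_threshold = 5L,
                       seed = NULL,
                       map_spec = chaotic_map_spec("logistic"),
                       switch_mode = c("toggle", "one_way"),
                       chaotic_x0 = NULL,
                       init_population = NULL) {
  variant <- match.arg(variant)
  switch_mode <- match.arg(switch_mode)
  bounds <- as_bounds(bounds, dimension)
  problems <- character(0)
  if (population_size < 2) problems <- c(problems, "population_size must be >= 2")
  if (max_iters < 1) problems <- c(problems, "max_iters must be >= 1")
  if (any(bounds[, 1] >= bounds[, 2])) {
    problems <- c(problems, "every bound pair needs low < high")
  }
  if (stagnation_threshold < 1) {
    problems <- c(problems, "stagnation_threshold must be >= 1")
  }
  if (!is.null(chaotic_x0) && !is_admissible_seed(chaotic_x0, map_spec$map_id)) {
    problems <- c(problems, "chaotic_x0 is a degenerate seed for the chosen map")
  }
  if (!is.null(init_population)) {
    init_population <- as.matrix(init_population)
    if (ncol(init_population) != dimension) {
      problems <- c(problems, "init_population must have `dimension` columns")
    }
    if (nrow(init_population) > population_size) {
      problems <- c(problems, "init_population has more rows than population_size")
    }
  }
  if (length(problems) > 0) {
    stop("invalid optimizer configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(
    list(variant = variant, dimension = as.integer(dimension), bounds = bounds,
         population_size = as.integer(population_size),
         max_iters = as.integer(max_iters), spiral_b = spiral_b,
         stagnation_threshold = as.integer(stagnation_threshold),
         seed = seed, map_spec = map_spec, switch_mode = switch_mode,
         chaotic_x0 = chaotic_x0, init_population = init_population),
    class = "woa_config")
}

as_bounds <- function(bounds, dimension) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  if (is.null(dim(bounds))) {
    if (length(bounds) != 2L) stop("bounds must be (low, high) pairs")
    bounds <- matrix(bounds, nrow = 1)
  }
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L) stop("bounds must be (low, high) pairs")
  if (nrow(bounds) == 1L && dimension > 1L) {
    bounds <- bounds[rep(1L, dimension), , drop = FALSE]
  }
  if (nrow(bounds) != dimension) {
    stop("need one bound pair per dimension (", dimension, "), got ",
         nrow(bounds))
  }
  unname(bounds)
}

#' Linear shrink schedule for the coefficient a
#'
#' `a = 2 * (1 - t / T)`: 2 at the start of the run, 0 at the end.
#'
#' @param t Iteration index, `0 <= t <= T`.
#' @param T_max Total iterations, `>= 1`.
#' @return A scalar in `[0, 2]`.
#' @export
linear_a <- function(t, T_max) {
  if (T_max < 1) stop("T_max must be >= 1")
  if (t < 0 || t > T_max) stop("t must lie in [0, T_max], got t = ", t)
  2 * (1 - t / T_max)
}

#' Coefficient vectors A and C
#'
#' `A = 2 a r - a` and `C = 2 r`, component-wise, for a random (or chaotic)
#' vector `r` in `[0, 1]^d`.
#'
#' @param a Shrink coefficient in `[0, 2]`.
#' @param r Vector of draws in `[0, 1]`.
#' @return List with components `A` and `C`.
#' @export
woa_coefficients <- function(a, r) {
  list(A = 2 * a * r - a, C = 2 * r)
}

#' Encircling move toward the leader
#'
#' `D = |C * Xstar - X|`, new position `Xstar - A * D` (all element-wise).
#'
#' @param X Current position.
#' @param Xstar Leader position.
#' @param A,C Coefficient vectors from [woa_coefficients()].
#' @return The updated position.
#' @export
woa_encircle <- function(X, Xstar, A, C) {
  check_same_length(X, Xstar, A, C)
  D <- abs(C * Xstar - X)
  Xstar - A * D
}

#' Logarithmic-spiral move around the leader
#'
#' `D' = |Xstar - X|`, new position `D' * exp(b l) * cos(2 pi l) + Xstar`.
#'
#' @param X Current position.
#' @param Xstar Leader position.
#' @param b Spiral shape constant.
#' @param l Scalar draw in `[-1, 1]`.
#' @return The updated position.
#' @export
woa_spiral <- function(X, Xstar, b, l) {
  check_same_length(X, Xstar)
  if (l < -1 || l > 1) stop("l must lie in [-1, 1]")
  Dp <- abs(Xstar - X)
  Dp * exp(b * l) * cos(2 * pi * l) + Xstar
}

#' Exploration move toward a random agent
#'
#' `D = |C * Xrand - X|`, new position `Xrand - A * D`. The random agent is
#' drawn uniformly over the whole population (self-selection allowed).
#'
#' @param X Current position.
#' @param Xrand Position of the randomly selected agent.
#' @param A,C Coefficient vectors.
#' @return The updated position.
#' @export
woa_explore <- function(X, Xrand, A, C) {
  check_same_length(X, Xrand, A, C)
  D <- abs(C * Xrand - X)
  Xrand - A * D
}

check_same_length <- function(...) {
  lens <- lengths(list(...))
  if (length(unique(lens)) != 1L) {
    stop("position/coefficient vectors must share one length, got ",
         paste(lens, collapse = ", "))
  }
  invisible(TRUE)
}

#' Select the move for one agent
#'
#' `p >= 0.5` chooses the spiral; otherwise `|A| < 1` exploits (encircle)
#' and `|A| >= 1` explores, where `A` is the scalar branch draw.
#'
#' @param p Scalar draw in `[0, 1]`.
#' @param A Scalar branch coefficient.
#' @return `"spiral"`, `"encircle"` or `"explore"`.
#' @export
select_move <- function(p, A) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p >= 0.5) "spiral" else if (abs(A) < 1) "encircle" else "explore"
}

#' Clip a position into the box bounds
#'
#' Coordinates beyond the search space are amended by clipping; the
#' operation is idempotent.
#'
#' @param X Position vector.
#' @param bounds Two-column bounds matrix.
#' @return The clipped position.
#' @export
amend_bounds <- function(X, bounds) {
  bounds <- as_bounds(bounds, length(X))
  pmin(pmax(X, bounds[, 1]), bounds[, 2])
}

#' Default random-draw sampler
#'
#' Wraps the R RNG in the draw interface consumed by [woa_step()]. Tests can
#' substitute a stub that replays frozen values.
#'
#' @return List of draw functions `r_scalar()`, `r_vec(d)`, `p()`, `l()`,
#'   `rand_index(n)`.
#' @export
default_sampler <- function() {
  list(
    r_scalar = function() stats::runif(1),
    r_vec = function(d) stats::runif(d),
    p = function() stats::runif(1),
    l = function() stats::runif(1, -1, 1),
    rand_index = function(n) sample.int(n, 1)
  )
}

new_woa_state <- function(positions, fitness, config) {
  best <- which.min(fitness)
  list(
    t = 0L,
    positions = positions,
    fitness = fitness,
    leader_position = positions[best, ],
    leader_fitness = fitness[best],
    previous_best_fitness = Inf,
    no_improvement_count = 0L,
    active_map = config$map_spec$map_id,
    chaotic_x = NA_real_,
    trace = numeric(0),
    map_trace = character(0),
    switch_events = integer(0)
  )
}

evaluate_fitness <- function(objective, positions) {
  vapply(seq_len(nrow(positions)), function(i) {
    f <- objective(positions[i, ])
    if (!is.finite(f)) {
      warning("objective returned a non-finite value; recorded as +Inf",
              call. = FALSE)
      f <- Inf
    }
    as.numeric(f)
  }, numeric(1))
}

#' One optimizer iteration
#'
#' Moves every agent by its selected branch (encircle / spiral / explore),
#' amends bounds, re-evaluates the objective, and replaces the leader only
#' on strict improvement. For the chaotic variants the chaotic number is
#' advanced once at the top of the iteration and shared across agents; for
#' DCWOA the stagnation counter is updated afterwards and may toggle the
#' active map.
#'
#' @param state Optimizer state, as produced by [woa_run()] internals.
#' @param objective Function of a position vector returning a scalar loss.
#' @param config A [woa_config()].
#' @param sampler Draw interface, [default_sampler()] unless stubbed.
#' @return The updated state.
#' @export
woa_step <- function(state, objective, config, sampler = default_sampler()) {
  a <- linear_a(state$t, config$max_iters)
  n <- nrow(state$positions)
  d <- ncol(state$positions)
  chaotic <- config$variant %in% c("cwoa", "dcwoa")
  if (chaotic) {
    spec <- config$map_spec
    spec$map_id <- state$active_map
    state$chaotic_x <- chaotic_step(state$chaotic_x, spec)
  }
  for (i in seq_len(n)) {
    r_s <- if (chaotic) state$chaotic_x else sampler$r_scalar()
    A_s <- 2 * a * r_s - a
    p <- sampler$p()
    l <- sampler$l()
    r_v <- if (chaotic) rep(state$chaotic_x, d) else sampler$r_vec(d)
    cf <- woa_coefficients(a, r_v)
    X <- state$positions[i, ]
    move <- select_move(p, A_s)
    newX <- switch(
      move,
      spiral = woa_spiral(X, state$leader_position, config$spiral_b, l),
      encircle = woa_encircle(X, state$leader_position, cf$A, cf$C),
      explore = {
        j <- sampler$rand_index(n)
        woa_explore(X, state$positions[j, ], cf$A, cf$C)
      }
    )
    state$positions[i, ] <- amend_bounds(newX, config$bounds)
  }
  state$fitness <- evaluate_fitness(objective, state$positions)
  best <- which.min(state$fitness)
  if (state$fitness[best] < state$leader_fitness) {
    state$leader_fitness <- state$fitness[best]
    state$leader_position <- state$positions[best, ]
  }
  state$t <- state$t + 1L
  state$trace <- c(state$trace, state$leader_fitness)
  if (config$variant == "dcwoa") {
    state <- update_stagnation(state, state$leader_fitness,
                               config$stagnation_threshold,
                               config$switch_mode)
  }
  state$map_trace <- c(state$map_trace,
                       if (chaotic) state$active_map else NA_character_)
  state
}

#' Stagnation bookkeeping and map switching
#'
#' Compares the current leader fitness with the best previously seen: no
#' strict improvement increments the stagnation counter, improvement resets
#' it and records the new best. When the counter exceeds `threshold` the
#' active chaotic map switches (logistic <-> sine under `"toggle"`), the
#' switch iteration is logged, and the counter resets to 0.
#'
#' @param state Optimizer state.
#' @param leader_fitness Best fitness after the current iteration.
#' @param threshold Stagnant iterations tolerated before a switch.
#' @param switch_mode `"toggle"` or `"one_way"`.
#' @return The updated state.
#' @export
update_stagnation <- function(state, leader_fitness, threshold = 5L,
                              switch_mode = "toggle") {
  if (threshold < 1) stop("threshold must be >= 1")
  if (leader_fitness >= state$previous_best_fitness) {
    state$no_improvement_count <- state$no_improvement_count + 1L
  } else {
    state$previous_best_fitness <- leader_fitness
    state$no_improvement_count <- 0L
  }
  if (state$no_improvement_count > threshold) {
    state$active_map <-
      if (switch_mode == "toggle") {
        if (state$active_map == "logistic") "sine" else "logistic"
      } else {
        "sine"
      }
    state$switch_events <- c(state$switch_events, state$t)
    state$no_improvement_count <- 0L
  }
  state
}

#' Run a whale optimizer
#'
#' Executes `max_iters` iterations of the configured variant over the box
#' bounds, minimizing `objective`. The initial population is uniform within
#' bounds from the seeded RNG (optionally partially pinned through
#' `init_population`); the chaotic seed, when needed, is drawn from the same
#' RNG stream. Fully reproducible per seed.
#'
#' @param objective Function of a position vector returning a scalar loss.
#' @param config A [woa_config()].
#' @param sampler Draw interface override, mainly for testing.
#' @return An object of class `woa_result`: list with `best_position`,
#'   `best_fitness`, `trace` (per-iteration best fitness, non-increasing),
#'   `initial_fitness`, `map_trace`, `switch_events` and the `config`.
#' @examples
#' res <- woa_run(function(x) sum(x^2),
#'                woa_config("dcwoa", dimension = 2, bounds = c(-5, 5),
#'                           max_iters = 30, seed = 1))
#' res$best_fitness
#' @export
woa_run <- function(objective, config, sampler = NULL) {
  stopifnot(inherits(config, "woa_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(sampler)) sampler <- default_sampler()

  n <- config$population_size
  d <- config$dimension
  lo <- config$bounds[, 1]
  hi <- config$bounds[, 2]
  positions <- matrix(stats::runif(n * d), nrow = n)
  positions <- sweep(sweep(positions, 2, hi - lo, "*"), 2, lo, "+")
  if (!is.null(config$init_population)) {
    k <- nrow(config$init_population)
    positions[seq_len(k), ] <- t(apply(config$init_population, 1,
                                       amend_bounds, config$bounds))
  }
  fitness <- evaluate_fitness(objective, positions)
  state <- new_woa_state(positions, fitness, config)
  if (config$variant %in% c("cwoa", "dcwoa")) {
    state$chaotic_x <- if (!is.null(config$chaotic_x0)) config$chaotic_x0
                       else draw_chaotic_seed(config$map_spec$map_id)
  }
  for (t in seq_len(config$max_iters)) {
    state <- woa_step(state, objective, config, sampler)
  }
  structure(
    list(best_position = state$leader_position,
         best_fitness = state$leader_fitness,
         trace = state$trace,
         initial_fitness = min(fitness),
         map_trace = state$map_trace,
         switch_events = state$switch_events,
         config = config),
    class = "woa_result")
}

#' @export
print.woa_result <- function(x, ...) {
  cat("<woa_result>", x$config$variant, "|",
      x$config$population_size, "whales x", x$config$max_iters, "iters\n")
  cat("  best fitness:", format(x$best_fitness, digits = 6), "\n")
  cat("  best position:", paste(format(x$best_position, digits = 4),
                                collapse = ", "), "\n")
  if (length(x$switch_events)) {
    cat("  map switches at iterations:",
        paste(x$switch_events, collapse = ", "), "\n")
  }
  invisible(x)
}
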