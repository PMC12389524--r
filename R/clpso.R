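#' Define a box-bounded search space
#'
#' @param lower,upper numeric vectors of per-dimension bounds
#'   (`lower < upper`).
#' @param kind per-dimension kind, `"real"` or `"integer"`. Integer
#'   dimensions keep a real-valued swarm position and are rounded only when
#'   a position is evaluated or reported.
#' @param names optional dimension names.
#' @return An object of class `search_space`.
#' @export
search_space <- function(lower, upper, kind = "real", names = NULL) {
  d <- length(lower)
  if (length(upper) != d) stop("lower and upper must match", call. = FALSE)
  if (!all(lower < upper)) stop("need lower < upper per dimension", call. = FALSE)
  kind <- rep_len(kind, d)
  if (!all(kind %in% c("real", "integer"))) {
    stop("kind must be 'real' or 'integer'", call. = FALSE)
  }
  names <- names %||% paste0("x", seq_len(d))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 kind = kind, names = names, n_dims = d),
            class = "search_space")
}

# Round integer dimensions; used at fitness evaluation and when reporting.
round_integers <- function(space, x) {
  ix <- space$kind == "integer"
  x[ix] <- pmin(space$upper[ix], pmax(space$lower[ix], round(x[ix])))
  x
}

# Exemplar learning probability of the comprehensive-learning strategy:
# an exponential ramp from 0.05 for the first particle to 0.5 for the last.
clpso_pc <- function(ps) {
  if (ps == 1L) return(0.05)
  i <- seq_len(ps)
  0.05 + 0.45 * (exp(10 * (i - 1) / (ps - 1)) - 1) / (exp(10) - 1)
}

#' Initialize a particle swarm
#'
#' Positions are uniform within bounds and velocities uniform in
#' `[-vmax, vmax]` where `vmax = velocity_clamp * (upper - lower)`. Uses the
#' ambient RNG; [clpso_optimize()] and [pso_optimize()] seed it for you.
#'
#' @param space a [search_space()].
#' @param n_particles swarm size.
#' @param fitness_fn objective to minimize (vector position -> scalar).
#' @param inertia_start,inertia_end linear inertia schedule over the
#'   evaluation budget.
#' @param c_cl comprehensive-learning acceleration constant.
#' @param c1,c2 plain-PSO acceleration constants.
#' @param refresh_gap stagnation count after which a particle's exemplars
#'   are reassigned.
#' @param velocity_clamp velocity bound as a fraction of the search range.
#' @param max_evaluations evaluation budget (used by the inertia schedule).
#' @return A `swarm_state` list.
#' @export
swarm_init <- function(space, n_particles, fitness_fn,
                       inertia_start = 0.9, inertia_end = 0.4,
                       c_cl = 1.49445, c1 = 1.49445, c2 = 1.49445,
                       refresh_gap = 7L, velocity_clamp = 0.2,
                       max_evaluations = 1000L) {
  ps <- as.integer(n_particles)
  d <- space$n_dims
  range <- space$upper - space$lower
  X <- matrix(stats::runif(ps * d), ps, d)
  X <- sweep(sweep(X, 2, range, "*"), 2, space$lower, "+")
  vmax <- velocity_clamp * range
  V <- matrix(stats::runif(ps * d, -1, 1), ps, d)
  V <- sweep(V, 2, vmax, "*")
  state <- list(space = space, positions = X, velocities = V,
                pbest = X, pbest_fitness = rep(Inf, ps),
                gbest = X[1, ], gbest_fitness = Inf,
                exemplar = matrix(rep(seq_len(ps), d), ps, d),
                stagnation = rep(refresh_gap + 1L, ps),  # force first assignment
                pc = clpso_pc(ps),
                inertia_start = inertia_start, inertia_end = inertia_end,
                c_cl = c_cl, c1 = c1, c2 = c2,
                refresh_gap = as.integer(refresh_gap), vmax = vmax,
                eval_count = 0L, max_evaluations = as.integer(max_evaluations),
                n_penalized = 0L, trace = numeric(0))
  class(state) <- "swarm_state"
  state <- evaluate_swarm(state, fitness_fn)
  assign_exemplars(state, force = TRUE)
}

# Evaluate all particles at their current positions and update the bests,
# stagnation counters, evaluation count and trace. Non-finite fitness is
# penalized with +Inf and counted.
evaluate_swarm <- function(state, fitness_fn) {
  ps <- nrow(state$positions)
  fit <- vapply(seq_len(ps), function(i) {
    f <- fitness_fn(round_integers(state$space, state$positions[i, ]))
    if (!is.finite(f)) {
      state$n_penalized <<- state$n_penalized + 1L
      f <- Inf
    }
    f
  }, numeric(1))
  improved <- fit < state$pbest_fitness
  state$pbest[improved, ] <- state$positions[improved, , drop = FALSE]
  state$pbest_fitness[improved] <- fit[improved]
  state$stagnation <- ifelse(improved, 0L, state$stagnation + 1L)
  best <- which.min(state$pbest_fitness)
  if (state$pbest_fitness[best] < state$gbest_fitness) {
    state$gbest <- state$pbest[best, ]
    state$gbest_fitness <- state$pbest_fitness[best]
  }
  state$eval_count <- state$eval_count + ps
  state$trace <- c(state$trace, rep(state$gbest_fitness, ps))
  state
}

current_inertia <- function(state) {
  frac <- min(1, state$eval_count / max(1, state$max_evaluations))
  state$inertia_start - (state$inertia_start - state$inertia_end) * frac
}

# Clamp positions to bounds; velocity is zeroed in clamped dimensions.
clamp_positions <- function(state) {
  lo <- matrix(state$space$lower, nrow(state$positions), state$space$n_dims,
               byrow = TRUE)
  hi <- matrix(state$space$upper, nrow(state$positions), state$space$n_dims,
               byrow = TRUE)
  out <- state$positions < lo | state$positions > hi
  state$velocities[out] <- 0
  state$positions <- pmin(pmax(state$positions, lo), hi)
  state
}

#' One plain PSO step
#'
#' Velocity update
#' \deqn{V \leftarrow \omega V + c_1 r_1 (pbest - X) + c_2 r_2 (gbest - X)}
#' followed by `X <- X + V`, bound clamping and fitness evaluation.
#'
#' @param state a `swarm_state`.
#' @param fitness_fn objective to minimize.
#' @param rand1,rand2 optional fixed random matrices (test hooks); fresh
#'   uniforms in \[0, 1\] per particle-dimension when `NULL`.
#' @return The updated state.
#' @export
pso_step <- function(state, fitness_fn, rand1 = NULL, rand2 = NULL) {
  ps <- nrow(state$positions)
  d <- state$space$n_dims
  r1 <- rand1 %||% matrix(stats::runif(ps * d), ps, d)
  r2 <- rand2 %||% matrix(stats::runif(ps * d), ps, d)
  gb <- matrix(state$gbest, ps, d, byrow = TRUE)
  state$velocities <- current_inertia(state) * state$velocities +
    state$c1 * r1 * (state$pbest - state$positions) +
    state$c2 * r2 * (gb - state$positions)
  vmax <- matrix(state$vmax, ps, d, byrow = TRUE)
  state$velocities <- pmin(pmax(state$velocities, -vmax), vmax)
  state$positions <- state$positions + state$velocities
  state <- clamp_positions(state)
  evaluate_swarm(state, fitness_fn)
}

#' Assign comprehensive-learning exemplars
#'
#' For each dimension of each selected particle: with probability `Pc_i` the
#' exemplar is the better (by pbest fitness) of two other particles drawn at
#' random; otherwise the particle's own pbest. If every dimension ends up
#' self-assigned, one random dimension is forced to another particle's
#' pbest. Only particles whose stagnation counter exceeds the refreshing gap
#' are reassigned unless `force = TRUE`.
#'
#' @param state a `swarm_state`.
#' @param learning_probabilities optional per-particle override of `Pc`.
#' @param force reassign every particle regardless of stagnation.
#' @return The updated state.
#' @export
assign_exemplars <- function(state, learning_probabilities = NULL,
                             force = FALSE) {
  ps <- nrow(state$positions)
  d <- state$space$n_dims
  pc <- learning_probabilities %||% state$pc
  stopifnot(all(pc >= 0 & pc <= 1))
  which_particles <- if (force) {
    seq_len(ps)
  } else {
    which(state$stagnation > state$refresh_gap)
  }
  if (ps == 1L) {
    state$exemplar[which_particles, ] <- 1L
    state$stagnation[which_particles] <- 0L
    return(state)
  }
  for (i in which_particles) {
    others <- seq_len(ps)[-i]
    ex <- rep(i, d)
    learn <- stats::runif(d) < pc[i]
    for (dim in which(learn)) {
      pick <- if (length(others) == 1L) c(others, others) else sample(others, 2L)
      ex[dim] <- if (state$pbest_fitness[pick[1L]] <=
                     state$pbest_fitness[pick[2L]]) pick[1L] else pick[2L]
    }
    if (all(ex == i)) {
      dim <- if (d == 1L) 1L else sample.int(d, 1L)
      ex[dim] <- if (length(others) == 1L) others else sample(others, 1L)
    }
    state$exemplar[i, ] <- ex
    state$stagnation[i] <- 0L
  }
  state
}

#' One comprehensive-learning PSO step
#'
#' Reassigns exemplars for stagnated particles, then updates each dimension
#' of each particle toward its exemplar's personal best:
#' \deqn{V_d \leftarrow \omega V_d + c \, r_d \,
#'   (pbest_{exemplar(d), d} - X_d)}
#' followed by velocity clamping, `X <- X + V`, bound clamping and fitness
#' evaluation.
#'
#' @param state a `swarm_state`.
#' @param fitness_fn objective to minimize.
#' @param rand optional fixed random matrix (test hook).
#' @return The updated state.
#' @export
clpso_step <- function(state, fitness_fn, rand = NULL) {
  state <- assign_exemplars(state)
  ps <- nrow(state$positions)
  d <- state$space$n_dims
  r <- rand %||% matrix(stats::runif(ps * d), ps, d)
  target <- matrix(0, ps, d)
  for (dim in seq_len(d)) {
    target[, dim] <- state$pbest[state$exemplar[, dim], dim]
  }
  state$velocities <- current_inertia(state) * state$velocities +
    state$c_cl * r * (target - state$positions)
  vmax <- matrix(state$vmax, ps, d, byrow = TRUE)
  state$velocities <- pmin(pmax(state$velocities, -vmax), vmax)
  state$positions <- state$positions + state$velocities
  state <- clamp_positions(state)
  evaluate_swarm(state, fitness_fn)
}

run_swarm <- function(fitness_fn, space, n_particles, max_evaluations, seed,
                      step_fn, ...) {
  if (max_evaluations < n_particles) {
    stop("max_evaluations must be at least n_particles", call. = FALSE)
  }
  with_seed(seed, {
    state <- swarm_init(space, n_particles, fitness_fn,
                        max_evaluations = max_evaluations, ...)
    while (state$eval_count + n_particles <= max_evaluations) {
      state <- step_fn(state, fitness_fn)
    }
    list(best_position = stats::setNames(
           round_integers(space, state$gbest), space$names),
         best_fitness = state$gbest_fitness,
         trace = state$trace,
         state = state)
  })
}

#' Optimize a function with CLPSO
#'
#' Runs initialization, exemplar assignment and comprehensive-learning steps
#' until the evaluation budget is exhausted. Deterministic for a fixed seed
#' and deterministic fitness.
#'
#' @param fitness_fn objective to minimize (vector position -> scalar;
#'   non-finite values are penalized with `+Inf`).
#' @param space a [search_space()].
#' @param n_particles swarm size.
#' @param max_evaluations total fitness-evaluation budget
#'   (>= `n_particles`; equal to it returns the best of the initial sample).
#' @param seed integer seed.
#' @param ... further arguments to [swarm_init()].
#' @return A list with `best_position` (integer dimensions rounded),
#'   `best_fitness`, `trace` (best-so-far fitness per evaluation) and the
#'   final `state`.
#' @export
clpso_optimize <- function(fitness_fn, space, n_particles = 20L,
                           max_evaluations = 1000L, seed = 1L, ...) {
  run_swarm(fitness_fn, space, n_particles, max_evaluations, seed,
            clpso_step, ...)
}

#' Optimize a function with plain PSO (baseline)
#'
#' @inheritParams clpso_optimize
#' @return As [clpso_optimize()].
#' @export
pso_optimize <- function(fitness_fn, space, n_particles = 20L,
                         max_evaluations = 1000L, seed = 1L, ...) {
  run_swarm(fitness_fn, space, n_particles, max_evaluations, seed, pso_step, ...)
}
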