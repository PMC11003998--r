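# Continuous bacterial-foraging optimizer.  One generation = a chemotaxis
# sweep (peer-guided flip plus up to Ns swim steps per individual), a
# health-ranked crossover reproduction, and an adaptive elimination-dispersal
# event.  Minimization throughout; the best value ever seen is recorded and is
# non-increasing across generations.

#' Optimizer control parameters
#'
#' @param pop_size Colony size S; must be even (reproduction splits halves).
#' @param generations Iteration budget T.
#' @param r Chaos coefficient of the logistic-sine initializer.
#' @param ped0 Initial elimination-dispersal probability.
#' @param pc Crossover probability applied to each lower-half individual at
#'   reproduction.
#' @param nc Chemotaxis sweeps per generation.
#' @param ns Swim cap: maximum extra moves while fitness keeps improving.
#' @param nre Generations between reproduction events.
#' @param ned Generations between elimination-dispersal events.
#' @param swarm Optional `swarm_params()` list; when supplied the classic
#'   attraction-repulsion term is added to the fitness used during chemotaxis
#'   acceptance (classic-foraging comparison mode, off by default).
#' @return A list of class `bfo_control`.
#' @export
bfo_control <- function(pop_size = 60L, generations = 1000L, r = 0.86,
                        ped0 = 0.8, pc = 0.2, nc = 1L, ns = 4L,
                        nre = 1L, ned = 1L, swarm = NULL) {
  pop_size <- as.integer(pop_size)
  if (pop_size < 2L || pop_size %% 2L != 0L) {
    stop("pop_size must be even and >= 2", call. = FALSE)
  }
  if (ped0 < 0 || ped0 > 1) stop("ped0 must be in [0, 1]", call. = FALSE)
  if (pc < 0 || pc > 1) stop("pc must be in [0, 1]", call. = FALSE)
  structure(list(pop_size = pop_size, generations = as.integer(generations),
                 r = r, ped0 = ped0, pc = pc, nc = as.integer(nc),
                 ns = as.integer(ns), nre = as.integer(nre),
                 ned = as.integer(ned), swarm = swarm),
            class = "bfo_control")
}

#' Swarm attraction-repulsion parameters
#'
#' Parameters of the classic cell-to-cell interaction term: attraction depth
#' and width, repulsion height and width, all non-negative.
#'
#' @param d_attract,w_attract,h_repellent,w_repellent Non-negative reals.
#' @return A list of class `swarm_params`.
#' @export
swarm_params <- function(d_attract = 0.1, w_attract = 0.2,
                         h_repellent = 0.1, w_repellent = 10) {
  vals <- c(d_attract, w_attract, h_repellent, w_repellent)
  if (any(vals < 0)) stop("swarm parameters must be non-negative", call. = FALSE)
  structure(list(d_attract = d_attract, w_attract = w_attract,
                 h_repellent = h_repellent, w_repellent = w_repellent),
            class = "swarm_params")
}

#' Cell-to-cell swarming term
#'
#' The classic combined attraction-repulsion potential evaluated at a point
#' against every colony member:
#' \deqn{J_{cc}(\theta) = \sum_i \left[-d_a e^{-w_a \|\theta-\theta^i\|^2}
#'   + h_r e^{-w_r \|\theta-\theta^i\|^2}\right]}
#' Exposed for the classic-foraging comparison mode; the default chemotaxis
#' replaces this group-communication mechanism with moves toward
#' better-scoring peers.
#'
#' @param theta Position vector.
#' @param positions Colony position matrix (rows = individuals).
#' @param sip A `swarm_params()` list.
#' @return The scalar interaction value.
#' @export
swarm_interaction <- function(theta, positions, sip) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1L)
  stopifnot(nrow(positions) >= 1L)
  d2 <- rowSums(sweep(positions, 2L, theta, "-")^2)
  sum(-sip$d_attract * exp(-sip$w_attract * d2) +
        sip$h_repellent * exp(-sip$w_repellent * d2))
}

#' Adaptive elimination-dispersal probability
#'
#' \deqn{P = \frac{|f_{min}| + |(f_{max} - f_i) P_{prev}|}
#'                {|f_{min}| + |(f_{max} - f_{min}) P_{prev}|}}
#' clamped to `[0, 1]`.  `f_min`/`f_max` are the historical extremes of the
#' score being tracked and `f_i` the individual's current score; an individual
#' sitting exactly at `f_min` gets probability 1.  The score is oriented so
#' that its numerical minimum is the *worst* individual (the minimizer passes
#' negated objective values; the structure learner passes log K2 health
#' scores, where larger is better).
#'
#' @param f_min,f_max Historical score extremes.
#' @param f_i Current score of the individual.
#' @param ped_prev Previous dispersal probability, in `[0, 1]`.
#' @return A probability in `[0, 1]`.  Degenerate denominators (e.g.
#'   `f_min = 0` with `ped_prev = 0`) return `ped_prev` unchanged.
#' @export
dispersal_probability <- function(f_min, f_max, f_i, ped_prev) {
  stopifnot(ped_prev >= 0, ped_prev <= 1)
  num <- abs(f_min) + abs((f_max - f_i) * ped_prev)
  den <- abs(f_min) + abs((f_max - f_min) * ped_prev)
  if (den == 0) return(ped_prev)
  min(max(num / den, 0), 1)
}

#' Chemotaxis target set
#'
#' Indices of the strictly better-scoring individuals, plus the best one, for
#' the flip move of individual `i` (minimization).
#'
#' @param fitness Numeric fitness vector for the colony.
#' @param i Index of the moving individual.
#' @return Integer vector of candidate target indices (never empty).
#' @export
select_targets <- function(fitness, i) {
  better <- which(fitness < fitness[i])
  out <- unique(c(better, which.min(fitness)))
  sort(out)
}

#' Two-point crossover of real or binary vectors
#'
#' The segment `(cuts[1], cuts[2]]` is taken from `donor`, the rest from
#' `base`.  Cut points are positions between coordinates, drawn uniformly
#' without replacement from `0:length(base)` when not supplied.
#'
#' @param base,donor Equal-length vectors.
#' @param cuts Optional two distinct integers in `0:length(base)`.
#' @return The offspring vector.
#' @export
two_point_crossover <- function(base, donor, cuts = NULL) {
  d <- length(base)
  stopifnot(length(donor) == d, d >= 1L)
  if (is.null(cuts)) cuts <- sample.int(d + 1L, 2L) - 1L
  cuts <- sort(as.integer(cuts))
  if (cuts[1] == cuts[2] || any(cuts < 0L) || any(cuts > d)) {
    stop("cuts must be two distinct positions in 0:length(base)", call. = FALSE)
  }
  out <- base
  seg <- seq.int(cuts[1] + 1L, cuts[2])
  out[seg] <- donor[seg]
  out
}

# --- colony -----------------------------------------------------------------

.new_colony <- function(positions, fitness, ped0, lower, upper, chaos) {
  s <- nrow(positions)
  b <- which.min(fitness)
  list(positions = positions, fitness = fitness,
       health = numeric(s), ped = rep(ped0, s),
       lower = lower, upper = upper, chaos = chaos,
       best_x = positions[b, ], best_f = fitness[b],
       hist_f_min = min(fitness), hist_f_max = max(fitness))
}

.clip <- function(X, lower, upper) {
  X <- pmax(X, matrix(lower, nrow(X), ncol(X), byrow = TRUE))
  pmin(X, matrix(upper, nrow(X), ncol(X), byrow = TRUE))
}

#' Single-individual chemotaxis move
#'
#' Reference implementation of the flip-and-swim move for one individual:
#' a target is drawn from `select_targets()`, the candidate position is
#' \eqn{x + r (SF - I x)} with per-dimension \eqn{r \sim U(0,1)} and
#' \eqn{I \in \{1, 2\}}, clipped to the box, and adopted only on strict
#' fitness improvement; on improvement the same step vector is re-applied
#' (swimming) up to `ns` further times while fitness keeps improving.
#' Cumulative health is incremented by the (post-move) fitness after each
#' attempted step.  `r_fixed`, `i_fixed` and `target` allow deterministic
#' testing.
#'
#' @param colony A colony list (see `bfo_optimize()` internals).
#' @param i Individual index.
#' @param objective Function mapping a position matrix to fitness values.
#' @param ns Swim cap.
#' @param r_fixed,i_fixed Optional fixed per-dimension step and intensity
#'   vectors.
#' @param target Optional fixed target index.
#' @return The updated colony.
#' @export
chemotaxis_move <- function(colony, i, objective, ns = 4L,
                            r_fixed = NULL, i_fixed = NULL, target = NULL) {
  d <- ncol(colony$positions)
  tgt <- if (is.null(target)) {
    cand_set <- select_targets(colony$fitness, i)
    cand_set[sample.int(length(cand_set), 1L)]
  } else target
  sf <- colony$positions[tgt, ]
  rr <- if (is.null(r_fixed)) stats::runif(d) else r_fixed
  ii <- if (is.null(i_fixed)) sample(c(1, 2), d, replace = TRUE) else i_fixed
  x <- colony$positions[i, ]
  delta <- rr * (sf - ii * x)
  for (step in seq_len(ns + 1L)) {
    cand <- colony$positions[i, ] + delta
    cand <- pmin(pmax(cand, colony$lower), colony$upper)
    f_new <- objective(matrix(cand, nrow = 1L))[[1L]]
    improved <- f_new < colony$fitness[i]
    if (improved) {
      colony$positions[i, ] <- cand
      colony$fitness[i] <- f_new
      if (f_new < colony$best_f) {
        colony$best_f <- f_new
        colony$best_x <- cand
      }
    }
    colony$health[i] <- colony$health[i] + colony$fitness[i]
    if (!improved) break
  }
  colony
}

# Vectorized chemotaxis sweep over the whole colony; same move semantics as
# chemotaxis_move() but proposes for all still-swimming individuals at once.
.chemotaxis_sweep <- function(colony, objective, ns, swarm = NULL) {
  X <- colony$positions
  s <- nrow(X); d <- ncol(X)
  eff <- function(F, P) {
    if (is.null(swarm)) return(F)
    F + vapply(seq_len(nrow(P)),
               function(k) swarm_interaction(P[k, ], colony$positions, swarm),
               numeric(1))
  }
  # Flip: one randomized move toward a better-scoring peer per individual.
  f <- colony$fitness
  ord <- order(f)
  m <- rank(f, ties.method = "min") - 1L   # count of strictly better peers
  tgt <- integer(s)
  has_better <- m > 0L
  tgt[!has_better] <- ord[1L]
  if (any(has_better)) {
    pick <- ceiling(stats::runif(sum(has_better)) * m[has_better])
    pick[pick < 1L] <- 1L
    tgt[has_better] <- ord[pick]
  }
  SF <- colony$positions[tgt, , drop = FALSE]
  R <- matrix(stats::runif(s * d), s, d)
  I <- matrix(1 + (stats::runif(s * d) < 0.5), s, d)
  delta <- R * (SF - I * colony$positions)
  active <- rep(TRUE, s)
  # Swim: re-apply the same step vector while fitness keeps improving.
  for (step in seq_len(ns + 1L)) {
    idx <- which(active)
    if (length(idx) == 0L) break
    Xi <- colony$positions[idx, , drop = FALSE]
    cand <- Xi + delta[idx, , drop = FALSE]
    cand <- .clip(cand, colony$lower, colony$upper)
    f_new <- objective(cand)
    improved <- eff(f_new, cand) < eff(colony$fitness[idx], Xi)
    if (any(improved)) {
      upd <- idx[improved]
      colony$positions[upd, ] <- cand[improved, , drop = FALSE]
      colony$fitness[upd] <- f_new[improved]
      bi <- which.min(colony$fitness)
      if (colony$fitness[bi] < colony$best_f) {
        colony$best_f <- colony$fitness[bi]
        colony$best_x <- colony$positions[bi, ]
      }
    }
    # Health accrues for the whole colony each round (sitting individuals
    # re-add their current fitness), keeping accumulation counts comparable
    # across individuals for the reproduction ranking.
    colony$health <- colony$health + colony$fitness
    active[idx] <- improved
  }
  colony$hist_f_min <- min(colony$hist_f_min, colony$fitness)
  colony$hist_f_max <- max(colony$hist_f_max, colony$fitness)
  colony
}

#' Health-ranked crossover reproduction
#'
#' Ranks the colony by cumulative health (lower accumulated objective =
#' healthier under minimization), keeps the elite half unchanged, and with
#' probability `pc` replaces each lower-half individual by a two-point
#' crossover offspring of itself (base) and its rank-matched elite (donor).
#' Health is reset to zero afterwards.
#'
#' @param colony Colony list.
#' @param pc Crossover probability.
#' @param objective Matrix objective for re-evaluating offspring.
#' @return The updated colony.
#' @export
reproduce_colony <- function(colony, pc, objective) {
  s <- nrow(colony$positions)
  if (s %% 2L != 0L) stop("colony size must be even", call. = FALSE)
  half <- s %/% 2L
  ord <- order(colony$health)
  elites <- ord[seq_len(half)]
  worsts <- ord[seq.int(half + 1L, s)]
  fire <- stats::runif(half) < pc
  if (any(fire)) {
    changed <- integer(0)
    for (k in which(fire)) {
      off <- two_point_crossover(colony$positions[worsts[k], ],
                                 colony$positions[elites[k], ])
      colony$positions[worsts[k], ] <- off
      changed <- c(changed, worsts[k])
    }
    f_new <- objective(colony$positions[changed, , drop = FALSE])
    colony$fitness[changed] <- f_new
    bi <- which.min(colony$fitness)
    if (colony$fitness[bi] < colony$best_f) {
      colony$best_f <- colony$fitness[bi]
      colony$best_x <- colony$positions[bi, ]
    }
    colony$hist_f_min <- min(colony$hist_f_min, f_new)
    colony$hist_f_max <- max(colony$hist_f_max, f_new)
  }
  colony$health <- numeric(s)
  colony
}

#' Elimination-dispersal over a whole colony
#'
#' Re-initializes each individual independently with its own dispersal
#' probability, drawing fresh chaotic positions.  Within `bfo_optimize()` the
#' per-generation event instead tests a single randomly selected individual
#' (see the package vignette); this whole-colony form is the building block
#' and is exposed for direct use.
#'
#' @param colony Colony list whose `ped` field holds current per-individual
#'   probabilities.
#' @param objective Matrix objective for re-evaluating dispersed individuals.
#' @return The updated colony.
#' @export
eliminate_disperse <- function(colony, objective) {
  s <- nrow(colony$positions)
  hit <- which(stats::runif(s) < colony$ped)
  if (length(hit) > 0L) {
    d <- ncol(colony$positions)
    span <- colony$upper - colony$lower
    for (i in hit) {
      colony$positions[i, ] <- colony$lower + colony$chaos(d) * span
    }
    f_new <- objective(colony$positions[hit, , drop = FALSE])
    colony$fitness[hit] <- f_new
    bi <- which.min(colony$fitness)
    if (colony$fitness[bi] < colony$best_f) {
      colony$best_f <- colony$fitness[bi]
      colony$best_x <- colony$positions[bi, ]
    }
    colony$hist_f_min <- min(colony$hist_f_min, f_new)
    colony$hist_f_max <- max(colony$hist_f_max, f_new)
  }
  colony
}

# Update every individual's adaptive dispersal probability.  Scores are
# negated objective values so the numerically worst individual sits at the
# historical score minimum and receives probability 1.
.update_ped <- function(colony) {
  s_min <- -colony$hist_f_max
  s_max <- -colony$hist_f_min
  colony$ped <- vapply(seq_along(colony$fitness), function(i) {
    dispersal_probability(s_min, s_max, -colony$fitness[i], colony$ped[i])
  }, numeric(1))
  colony
}

#' Run the bacterial-foraging optimizer
#'
#' Minimizes `objective` over a box.  `objective` may be a benchmark id from
#' `benchmark_ids()` (bounds and dimension taken from its spec) or a function;
#' functions are called with an S x D matrix and must return S values unless
#' `vectorized = FALSE`, in which case a plain single-vector function is
#' wrapped row-wise.
#'
#' @param objective Benchmark id or objective function.
#' @param lower,upper Bound vectors (ignored for benchmark ids).
#' @param control A `bfo_control()` list.
#' @param seed Optional integer seed; when supplied the run is reproducible.
#' @param vectorized Whether a function objective accepts a position matrix.
#' @return A list of class `bfo_result`: `best_x`, `best_f`, `history`
#'   (per-generation best value, non-increasing), `evaluations`, `control`.
#' @export
bfo_optimize <- function(objective, lower = NULL, upper = NULL,
                         control = bfo_control(), seed = NULL,
                         vectorized = TRUE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.character(objective)) {
    spec <- benchmark_spec(objective)
    lower <- spec$lower; upper <- spec$upper
    id <- spec$id
    fn <- function(X) benchmark_evaluate(id, X)
  } else if (is.function(objective)) {
    if (is.null(lower) || is.null(upper)) {
      stop("lower and upper bounds are required for a function objective",
           call. = FALSE)
    }
    fn <- if (vectorized) objective else {
      function(X) apply(X, 1L, objective)
    }
  } else {
    stop("objective must be a benchmark id or a function", call. = FALSE)
  }
  stopifnot(length(lower) == length(upper), all(lower < upper))

  s <- control$pop_size
  chaos <- .chaos_stream(control$r)
  span <- upper - lower
  X0 <- matrix(chaos(s * length(lower)), nrow = s, byrow = TRUE)
  X0 <- sweep(sweep(X0, 2L, span, "*"), 2L, lower, "+")
  colony <- .new_colony(X0, fn(X0), control$ped0, lower, upper, chaos)

  history <- numeric(control$generations)
  n_eval <- s
  for (g in seq_len(control$generations)) {
    for (sweep_i in seq_len(control$nc)) {
      colony <- .chemotaxis_sweep(colony, fn, control$ns, control$swarm)
    }
    if (g %% control$nre == 0L) {
      colony <- reproduce_colony(colony, control$pc, fn)
    }
    if (g %% control$ned == 0L) {
      colony <- .update_ped(colony)
      pick <- sample.int(s, 1L)
      if (stats::runif(1) < colony$ped[pick]) {
        colony$positions[pick, ] <- lower + colony$chaos(length(lower)) * span
        f_new <- fn(colony$positions[pick, , drop = FALSE])
        colony$fitness[pick] <- f_new
        if (f_new < colony$best_f) {
          colony$best_f <- f_new
          colony$best_x <- colony$positions[pick, ]
        }
        colony$hist_f_min <- min(colony$hist_f_min, f_new)
        colony$hist_f_max <- max(colony$hist_f_max, f_new)
      }
    }
    history[g] <- colony$best_f
  }
  structure(list(best_x = colony$best_x, best_f = colony$best_f,
                 history = history, control = control),
            class = "bfo_result")
}

#' @export
print.bfo_result <- function(x, ...) {
  cat(sprintf("bacterial-foraging run: best f = %.6g after %d generations\n",
              x$best_f, length(x$history)))
  invisible(x)
}
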