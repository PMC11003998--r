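make_test_colony <- function(positions, fitness, ped0 = 0.8,
                             lower = NULL, upper = NULL) {
  d <- ncol(positions)
  if (is.null(lower)) lower <- rep(-10, d)
  if (is.null(upper)) upper <- rep(10, d)
  bfodbn:::.new_colony(positions, fitness, ped0, lower, upper,
                       bfodbn:::.chaos_stream(0.86))
}

sphere <- function(X) rowSums(X^2)

test_that("swarm interaction matches the attraction-repulsion closed form", {
  sip <- swarm_params(d_attract = 0.3, w_attract = 0.2,
                      h_repellent = 0.15, w_repellent = 10)
  # one bacterium, evaluated at its own position: -d + h
  expect_equal(swarm_interaction(c(1, 2), matrix(c(1, 2), 1), sip),
               -0.3 + 0.15)
  # equal depths and widths cancel pairwise
  sip_eq <- swarm_params(0.2, 3, 0.2, 3)
  set.seed(1)
  P <- matrix(rnorm(10), 5, 2)
  expect_equal(swarm_interaction(rnorm(2), P, sip_eq), 0)
  # all-zero magnitudes give zero
  expect_equal(swarm_interaction(c(0, 0), P, swarm_params(0, 1, 0, 1)), 0)
  expect_error(swarm_params(-1, 1, 1, 1), "non-negative")
})

test_that("target sets contain strictly better peers plus the best", {
  f <- c(1, 2, 3)
  expect_identical(select_targets(f, 1), 1L)        # the best: itself only
  expect_identical(select_targets(f, 3), c(1L, 2L)) # worst of 3: other two
  expect_identical(select_targets(f, 2), 1L)
  expect_identical(select_targets(rep(5, 4), 2), 1L) # all tied: best index
})

test_that("the dispersal probability follows the substitution identities", {
  # direct substitution: (|-2| + |0 * 0.8|) / (|-2| + |6 * 0.8|)
  expect_equal(dispersal_probability(-2, 4, 4, 0.8), 2 / 6.8,
               tolerance = 1e-9)
  expect_equal(dispersal_probability(-2, 4, 4, 0.8), 0.294118,
               tolerance = 1e-5)
  # at the historical minimum the ratio is exactly 1
  expect_equal(dispersal_probability(-2, 4, -2, 0.8), 1)
  expect_equal(dispersal_probability(3, 9, 3, 0.5), 1)
  # degenerate range: numerator = denominator = |f_min|
  expect_equal(dispersal_probability(5, 5, 5, 0.7), 1)
  # 0/0 guard returns the previous probability
  expect_equal(dispersal_probability(0, 0, 0, 0), 0)
  expect_equal(dispersal_probability(0, 0, 0, 0.4), 0.4)
  # range property over random finite inputs
  set.seed(3)
  for (k in 1:50) {
    v <- sort(rnorm(3, sd = 100))
    p <- dispersal_probability(v[1], v[3], v[2], runif(1))
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("two-point crossover degenerates as expected at the boundaries", {
  base <- 1:6; donor <- 11:16
  # cuts at the vector ends: whole segment from the donor
  expect_identical(two_point_crossover(base, donor, cuts = c(0, 6)),
                   donor)
  # empty-interior cuts
  expect_identical(two_point_crossover(base, donor, cuts = c(2, 4)),
                   c(1L, 2L, 13L, 14L, 5L, 6L))
  # D = 1: the only cut pair swaps the single coordinate
  expect_identical(two_point_crossover(5, 9), 9)
  expect_error(two_point_crossover(base, donor, cuts = c(3, 3)), "distinct")
})

test_that("chemotaxis keeps the position unless the move strictly improves", {
  pos <- matrix(c(1, 1, 3, 3), 2, 2, byrow = TRUE)
  col <- make_test_colony(pos, sphere(pos))
  # all r = 0: candidate equals the current position, no strict improvement
  out <- chemotaxis_move(col, 2, sphere, ns = 0, r_fixed = c(0, 0))
  expect_identical(out$positions, col$positions)
  # all r = 1, I = 1: candidate = SF exactly
  out <- chemotaxis_move(col, 2, sphere, ns = 0, r_fixed = c(1, 1),
                         i_fixed = c(1, 1), target = 1)
  expect_equal(out$positions[2, ], c(1, 1))
  expect_equal(out$fitness[2], 2)
  # a worsening candidate is rejected (move individual 1 toward worse 2)
  col2 <- make_test_colony(pos, sphere(pos))
  out <- chemotaxis_move(col2, 1, sphere, ns = 0, r_fixed = c(1, 1),
                         i_fixed = c(1, 1), target = 2)
  expect_equal(out$positions[1, ], c(1, 1))
})

test_that("reproduction preserves size, resets health, and pc = 0 is a no-op", {
  set.seed(11)
  pos <- matrix(runif(12, -5, 5), 6, 2)
  col <- make_test_colony(pos, sphere(pos))
  col$health <- runif(6)
  out <- reproduce_colony(col, pc = 0, sphere)
  expect_identical(out$positions, col$positions)
  expect_identical(out$health, numeric(6))
  out2 <- reproduce_colony(col, pc = 1, sphere)
  expect_identical(nrow(out2$positions), 6L)
  expect_equal(out2$fitness, sphere(out2$positions))
  odd <- make_test_colony(pos[1:5, ], sphere(pos[1:5, ]))
  expect_error(reproduce_colony(odd, 0.2, sphere), "even")
})

test_that("whole-colony dispersal honours the per-individual probabilities", {
  set.seed(21)
  pos <- matrix(runif(12, -5, 5), 6, 2)
  col <- make_test_colony(pos, sphere(pos))
  col$ped <- rep(0, 6)
  expect_identical(eliminate_disperse(col, sphere)$positions, col$positions)
  col$ped <- rep(1, 6)
  out <- eliminate_disperse(col, sphere)
  expect_false(any(out$positions == col$positions))
  expect_true(all(out$positions >= -10 & out$positions <= 10))
  # seedable (the chaotic stream is part of the colony state, so rebuild)
  mk <- function() {
    set.seed(33)
    cc <- make_test_colony(pos, sphere(pos))
    cc$ped <- rep(1, 6)
    eliminate_disperse(cc, sphere)
  }
  expect_identical(mk()$positions, mk()$positions)
})

test_that("runs are elitist, feasible, reproducible, and solve easy problems", {
  ctrl <- bfo_control(pop_size = 10, generations = 60)
  res <- bfo_optimize(function(X) rowSums((X - 3)^2), lower = -10, upper = 10,
                      control = ctrl, seed = 1)
  expect_length(res$history, 60)
  expect_true(!is.unsorted(rev(res$history)))   # non-increasing best value
  res2 <- bfo_optimize(function(X) rowSums((X - 3)^2), lower = -10,
                       upper = 10, control = ctrl, seed = 1)
  expect_identical(res$history, res2$history)
  # constant objective: best equals the constant from generation 1
  resc <- bfo_optimize(function(X) rep(7, nrow(X)), lower = 0, upper = 1,
                       control = bfo_control(pop_size = 4, generations = 5),
                       seed = 2)
  expect_true(all(resc$history == 7))
  # 1-D quadratic reaches 1e-6 under default-style settings
  hits <- vapply(1:10, function(s) {
    bfo_optimize(function(X) (X[, 1] - 3)^2, lower = -10, upper = 10,
                 control = bfo_control(pop_size = 20, generations = 200),
                 seed = s)$best_f < 1e-6
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("a pure accept-if-better reduction never worsens any individual", {
  # pc = 0, ped0 = 0, ns = 1: independent hill climbers toward sampled peers
  set.seed(9)
  ctrl <- bfo_control(pop_size = 8, generations = 1, pc = 0, ped0 = 0,
                      ns = 1)
  pos <- matrix(runif(16, -5, 5), 8, 2)
  col <- make_test_colony(pos, sphere(pos), ped0 = 0,
                          lower = rep(-5, 2), upper = rep(5, 2))
  before <- col$fitness
  out <- bfodbn:::.chemotaxis_sweep(col, sphere, ns = 1)
  expect_true(all(out$fitness <= before))
  expect_true(all(out$positions >= -5 & out$positions <= 5))
  expect_identical(nrow(out$positions), 8L)
})
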