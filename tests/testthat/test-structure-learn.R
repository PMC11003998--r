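toy_data <- local({
  env <- new.env()
  function(n_seq = 200, seed = 11) {
    key <- paste0("d", n_seq, "_", seed)
    if (is.null(env[[key]])) {
      env[[key]] <- forward_sample(toy_network(seed = 1), n_seq, 2,
                                   seed = seed)
    }
    env[[key]]
  }
})

test_that("edge operations enforce every validity rule with distinct codes", {
  A <- matrix(0L, 2, 2)
  res <- apply_edge_op(A, "add", 1, 2)
  expect_true(res$ok)
  expect_identical(res$graph[1, 2], 1L)
  # bidirectional
  res2 <- apply_edge_op(res$graph, "add", 2, 1)
  expect_false(res2$ok); expect_identical(res2$reason, "bidirectional")
  expect_identical(res2$graph, res$graph)
  # cycle: 1->2, 2->3 exists; adding 3->1 closes a cycle
  B <- matrix(0L, 3, 3); B[1, 2] <- B[2, 3] <- 1L
  res3 <- apply_edge_op(B, "add", 3, 1)
  expect_false(res3$ok); expect_identical(res3$reason, "cycle")
  # reverse 1->2 in {1->2, 2->3} is valid: {2->1, 2->3}
  res4 <- apply_edge_op(B, "reverse", 1, 2)
  expect_true(res4$ok)
  expect_identical(res4$graph[2, 1], 1L)
  expect_identical(res4$graph[1, 2], 0L)
  expect_true(dag_is_acyclic(res4$graph))
  # remove / reverse a missing edge
  expect_identical(apply_edge_op(B, "remove", 3, 1)$reason, "absent")
  expect_identical(apply_edge_op(B, "reverse", 3, 1)$reason, "absent")
  # self edge and parent cap
  expect_identical(apply_edge_op(B, "add", 2, 2)$reason, "self")
  C <- matrix(0L, 3, 3); C[1, 3] <- C[2, 3] <- 1L
  expect_identical(apply_edge_op(C, "add", 2, 1, max_parents = 1)$reason,
                   "ok")
  D <- matrix(0L, 3, 3); D[1, 2] <- 1L
  expect_identical(apply_edge_op(D, "add", 3, 2, max_parents = 1)$reason,
                   "max_parents")
  # temporal: in a 2n = 4 transition graph no head may be in slice t
  T4 <- matrix(0L, 4, 4)
  expect_identical(apply_edge_op(T4, "add", 3, 1, n_slice = 2)$reason,
                   "temporal")
  expect_true(apply_edge_op(T4, "add", 1, 3, n_slice = 2)$ok)
  t5 <- apply_edge_op(T4, "add", 1, 3, n_slice = 2)$graph
  expect_identical(apply_edge_op(t5, "reverse", 1, 3, n_slice = 2)$reason,
                   "temporal")
})

test_that("initial populations are valid, seeded, and inside the DAG space", {
  ds <- toy_data()
  ctrl <- dbn_control(pop_size = 20, generations = 1)
  set.seed(5)
  pop <- init_structures(3, ds, ctrl)
  expect_length(pop, 20)
  space <- vapply(enumerate_dags(3), function(A) paste(A, collapse = ""),
                  character(1))
  for (cand in pop) {
    expect_true(dag_is_acyclic(cand$b0))
    expect_true(check_temporal(cand$btrans, 3))
    expect_true(paste(cand$b0, collapse = "") %in% space)
    expect_false(is.na(cand$score))
    expect_equal(cand$hs, cand$k2_init)
  }
  set.seed(5)
  pop2 <- init_structures(3, ds, ctrl)
  expect_identical(lapply(pop, `[[`, "b0"), lapply(pop2, `[[`, "b0"))
})

test_that("structure chemotaxis is score-monotone and fixed at the best", {
  ds <- toy_data()
  ctrl <- dbn_control(pop_size = 10, generations = 1)
  scorer <- bfodbn:::.make_scorer(ds, ctrl$max_parents)
  set.seed(6)
  pop <- init_structures(3, ds, ctrl)
  scores_before <- vapply(pop, `[[`, numeric(1), "score")
  best_idx <- which.max(scores_before)
  # the best candidate's only target is itself: zero differences, no move
  out_best <- structure_chemotaxis(best_idx, pop, scorer, ctrl)
  expect_identical(out_best$b0, pop[[best_idx]]$b0)
  expect_identical(out_best$score, pop[[best_idx]]$score)
  for (i in seq_along(pop)) {
    out <- structure_chemotaxis(i, pop, scorer, ctrl)
    expect_gte(out$score, scores_before[i])
    expect_true(dag_is_acyclic(out$b0))
    expect_true(check_temporal(out$btrans, 3))
  }
})

test_that("a two-candidate pair differing by one edge proposes that flip", {
  ds <- toy_data()
  ctrl <- dbn_control(pop_size = 2, generations = 1)
  scorer <- bfodbn:::.make_scorer(ds, ctrl$max_parents)
  empty_bt <- matrix(0L, 6, 6)
  worse <- list(b0 = matrix(0L, 3, 3), btrans = empty_bt)
  A <- matrix(0L, 3, 3); A[1, 2] <- 1L
  better <- list(b0 = A, btrans = empty_bt)
  worse <- bfodbn:::.score_candidate(worse, scorer)
  better <- bfodbn:::.score_candidate(better, scorer)
  expect_gt(better$score, worse$score)   # coupled data: edge helps
  worse$hs <- worse$k2_init; better$hs <- better$k2_init
  set.seed(2)
  out <- structure_chemotaxis(1, list(worse, better), scorer, ctrl)
  # the only difference is the 1->2 edge; the move must adopt it
  expect_identical(out$b0, A)
  expect_equal(out$score, better$score)
})

test_that("health accumulates the transition term of each accepted step", {
  ds <- toy_data()
  ctrl <- dbn_control(pop_size = 4, generations = 1, ns = 0)
  scorer <- bfodbn:::.make_scorer(ds, ctrl$max_parents)
  set.seed(13)
  pop <- init_structures(3, ds, ctrl)
  for (i in seq_along(pop)) {
    before <- pop[[i]]
    out <- structure_chemotaxis(i, pop, scorer, ctrl)
    if (identical(out$b0, before$b0) &&
        identical(out$btrans, before$btrans)) {
      expect_identical(structure_health(out), structure_health(before))
    } else {
      expect_equal(structure_health(out),
                   structure_health(before) + out$k2_trans)
    }
  }
})

test_that("structure reproduction keeps size, validity, and pc = 0 is a no-op", {
  ds <- toy_data()
  ctrl0 <- dbn_control(pop_size = 10, generations = 1, pc = 0)
  scorer <- bfodbn:::.make_scorer(ds, ctrl0$max_parents)
  set.seed(19)
  pop <- init_structures(3, ds, ctrl0)
  out <- reproduce_structures(pop, scorer, ctrl0)
  expect_identical(lapply(out, `[[`, "b0"), lapply(pop, `[[`, "b0"))
  expect_equal(vapply(out, `[[`, numeric(1), "hs"),
               vapply(out, `[[`, numeric(1), "k2_init"))
  ctrl1 <- dbn_control(pop_size = 10, generations = 1, pc = 1)
  out1 <- reproduce_structures(pop, scorer, ctrl1)
  expect_length(out1, 10)
  for (cand in out1) {
    expect_true(dag_is_acyclic(cand$b0))
    expect_true(check_temporal(cand$btrans, 3))
    expect_equal(cand$score, cand$k2_init + cand$k2_trans)
  }
})

test_that("crossover of identical parents reproduces the parent; repair drops invalid bits", {
  b0 <- decode_graph("11|01|00", 3)$adjacency
  bt <- decode_graph("00110|00011|00001|00010|00001|00000", 6,
                     require_dag = FALSE)$adjacency
  bits <- candidate_bits(b0, bt)
  off <- two_point_crossover(bits, bits, cuts = c(2, 20))
  expect_identical(off, bits)
  # cuts isolating the first row of b0: "11|01|00" x empty -> "11|00|00"
  empty_bits <- candidate_bits(matrix(0L, 3, 3), matrix(0L, 6, 6))
  off2 <- two_point_crossover(b0_donor <- empty_bits, bits, cuts = c(0, 2))
  rebuilt <- bfodbn:::.repair_bits(off2[1:6], 3)
  expect_identical(encode_graph(dbn_graph(rebuilt)), "11|00|00")
  # repair clears the bit that would close the 1->2->3->1 cycle
  bad <- c(1L, 0L, 0L, 1L, 1L, 0L)   # cells (1,2), (2,3), (3,1)
  fixed <- bfodbn:::.repair_bits(bad, 3)
  expect_true(dag_is_acyclic(fixed))
  expect_identical(fixed[1, 2], 1L)
  expect_identical(fixed[2, 3], 1L)
  expect_identical(fixed[3, 1], 0L)
})

test_that("structure dispersal follows the health substitution identity and spares the best", {
  # direct substitution: (100 + 0) / (100 + 48)
  expect_equal(dispersal_probability(-100, -40, -40, 0.8), 100 / 148,
               tolerance = 1e-9)
  expect_equal(dispersal_probability(-100, -40, -40, 0.8), 0.675676,
               tolerance = 1e-6)
  expect_equal(dispersal_probability(-100, -40, -100, 0.8), 1)
  ds <- toy_data()
  ctrl <- dbn_control(pop_size = 10, generations = 1)
  scorer <- bfodbn:::.make_scorer(ds, ctrl$max_parents)
  set.seed(23)
  pop <- init_structures(3, ds, ctrl)
  scores <- vapply(pop, `[[`, numeric(1), "score")
  best_idx <- which.max(scores)
  hs <- vapply(pop, `[[`, numeric(1), "hs")
  out <- structure_dispersal(pop, min(hs), max(hs), scorer, ctrl)
  expect_identical(out[[best_idx]]$b0, pop[[best_idx]]$b0)
  expect_length(out, 10)
  for (cand in out) {
    expect_true(dag_is_acyclic(cand$b0))
    expect_true(check_temporal(cand$btrans, 3))
  }
})

test_that("learning improves monotonically and recovers the toy structure", {
  ds <- toy_data(400, seed = 31)
  fit <- dbn_learn(ds, dbn_control(pop_size = 12, generations = 30),
                   seed = 3)
  expect_length(fit$history, 30)
  expect_true(!is.unsorted(fit$history))
  expect_true(dag_is_acyclic(fit$network$b0))
  expect_true(check_temporal(fit$network$btrans, 3))
  expect_equal(fit$score, fit$k2_initial + fit$k2_transition)
  # reproducibility
  fit2 <- dbn_learn(ds, dbn_control(pop_size = 12, generations = 30),
                    seed = 3)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$network$b0$adjacency, fit2$network$b0$adjacency)
  # the learned initial network is close to the generating one
  expect_lte(shd(toy_network(seed = 1)$b0, fit$network$b0)$shd, 2)
})

test_that("a tiny elitist population reduces to hill climbing", {
  ds <- toy_data(150, seed = 37)
  fit <- dbn_learn(ds, dbn_control(pop_size = 2, generations = 20, pc = 0,
                                   ped0 = 0),
                   seed = 8)
  expect_true(!is.unsorted(fit$history))
  expect_true(dag_is_acyclic(fit$network$b0))
})
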