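# Score-guided structure search for 2T-BNs.  A population of candidate
# networks evolves under the same foraging framework as the continuous
# optimizer: chemotaxis adopts edge differences from better-scoring peers
# (add / remove / reverse operations, validity-checked), reproduction crosses
# poor candidates with elites on the bitstring encoding, and elimination-
# dispersal re-initializes candidates with an adaptive probability driven by
# accumulated health scores.  The dynamic K2 score is maximized.

#' Structure-learner control parameters
#'
#' @param pop_size Population size S (even).
#' @param generations Iteration budget T.
#' @param r Chaos coefficient of the logistic-sine edge initializer.
#' @param ped0 Initial dispersal probability.
#' @param pc Crossover probability at reproduction.
#' @param ns Swim cap per chemotaxis sweep.
#' @param nc Chemotaxis sweeps per generation.
#' @param nre Generations between reproduction events.
#' @param ned Generations between dispersal events.
#' @param max_parents Per-node parent cap (bounds the K2 configuration count).
#' @param p_edge Edge inclusion probability of the chaotic initializer.
#' @return A list of class `dbn_control`.
#' @export
dbn_control <- function(pop_size = 60L, generations = 100L, r = 0.86,
                        ped0 = 0.8, pc = 0.2, ns = 4L, nc = 1L,
                        nre = 1L, ned = 1L, max_parents = 4L, p_edge = 0.25) {
  pop_size <- as.integer(pop_size)
  if (pop_size < 2L || pop_size %% 2L != 0L) {
    stop("pop_size must be even and >= 2", call. = FALSE)
  }
  structure(list(pop_size = pop_size, generations = as.integer(generations),
                 r = r, ped0 = ped0, pc = pc, ns = as.integer(ns),
                 nc = as.integer(nc), nre = as.integer(nre),
                 ned = as.integer(ned), max_parents = as.integer(max_parents),
                 p_edge = p_edge),
            class = "dbn_control")
}

# --- edge operations --------------------------------------------------------

#' Apply an edge operation to a graph of a candidate network
#'
#' The three structure-search moves: `add` sets a_ij = 1, `remove` clears an
#' existing edge, `reverse` replaces a_ij by a_ji.  A proposal is rejected
#' (graph returned unchanged, with a reason code) when it would create a
#' self-loop, a bidirectional pair, a cycle, violate the temporal rule of a
#' transition graph (an edge into a slice-t node), exceed the parent cap, or
#' act on a missing edge.
#'
#' @param A Adjacency matrix (the initial graph, or the 2n x 2n transition
#'   graph).
#' @param op One of `"add"`, `"remove"`, `"reverse"`.
#' @param i,j Tail and head node indices of the edge a_ij.
#' @param n_slice For transition graphs, the per-slice node count n (heads
#'   must be slice-t+1 nodes, i.e. index > n); `NULL` for initial graphs.
#' @param max_parents Parent cap.
#' @return A list: `ok` (logical), `graph` (updated or original matrix),
#'   `reason` (`"ok"` or a rejection code: `"self"`, `"absent"`,
#'   `"exists"`, `"bidirectional"`, `"cycle"`, `"temporal"`,
#'   `"max_parents"`).
#' @export
apply_edge_op <- function(A, op, i, j, n_slice = NULL, max_parents = 4L) {
  reject <- function(reason) list(ok = FALSE, graph = A, reason = reason)
  if (i == j) return(reject("self"))
  temporal_ok <- function(head) is.null(n_slice) || head > n_slice
  # acyclicity scope: the whole graph for initial networks, the slice-t+1
  # induced subgraph for transition networks (slice-t nodes are sources)
  acyclic_ok <- function(M) {
    if (is.null(n_slice)) return(dag_is_acyclic(M))
    idx <- (n_slice + 1L):(2L * n_slice)
    dag_is_acyclic(M[idx, idx, drop = FALSE])
  }
  if (op == "add") {
    if (A[i, j] == 1L) return(reject("exists"))
    if (A[j, i] == 1L) return(reject("bidirectional"))
    if (!temporal_ok(j)) return(reject("temporal"))
    if (sum(A[, j]) >= max_parents) return(reject("max_parents"))
    A2 <- A; A2[i, j] <- 1L
    if (!acyclic_ok(A2)) return(reject("cycle"))
    return(list(ok = TRUE, graph = A2, reason = "ok"))
  }
  if (op == "remove") {
    if (A[i, j] == 0L) return(reject("absent"))
    A2 <- A; A2[i, j] <- 0L
    return(list(ok = TRUE, graph = A2, reason = "ok"))
  }
  if (op == "reverse") {
    if (A[i, j] == 0L) return(reject("absent"))
    if (!temporal_ok(i)) return(reject("temporal"))
    if (sum(A[, i]) >= max_parents) return(reject("max_parents"))
    A2 <- A; A2[i, j] <- 0L; A2[j, i] <- 1L
    if (!acyclic_ok(A2)) return(reject("cycle"))
    return(list(ok = TRUE, graph = A2, reason = "ok"))
  }
  stop("unknown edge operation: ", op, call. = FALSE)
}

# --- encoding of a candidate ------------------------------------------------

# Off-diagonal cells in fixed row-major order, as an index matrix.
.offdiag_cells <- function(n) {
  cells <- expand.grid(j = seq_len(n), i = seq_len(n))[, c("i", "j")]
  cells <- cells[cells$i != cells$j, ]
  cells <- cells[order(cells$i, cells$j), ]
  as.matrix(cells)
}

.graph_bits <- function(A) {
  n <- nrow(A)
  cells <- .offdiag_cells(n)
  A[cells]
}

# Rebuild a valid graph from a bit vector, scanning cells in fixed row-major
# order and dropping any set bit whose edge would violate validity.
.repair_bits <- function(bits, n, n_slice = NULL, max_parents = 4L) {
  cells <- .offdiag_cells(n)
  A <- matrix(0L, n, n)
  for (k in which(bits == 1L)) {
    res <- apply_edge_op(A, "add", cells[k, 1L], cells[k, 2L],
                         n_slice = n_slice, max_parents = max_parents)
    if (res$ok) A <- res$graph
  }
  A
}

#' Encoding of a candidate 2T-BN
#'
#' Concatenates the row-wise off-diagonal bits of the initial graph and the
#' transition graph into one integer vector (the crossover genome).
#'
#' @param b0,btrans Adjacency matrices (n x n and 2n x 2n).
#' @return Integer 0/1 vector of length `n(n-1) + 2n(2n-1)`.
#' @export
candidate_bits <- function(b0, btrans) {
  c(.graph_bits(b0), .graph_bits(btrans))
}

# --- scorer -----------------------------------------------------------------

# Precomputes record matrices and owns the family cache for one dataset.
.make_scorer <- function(dataset, max_parents) {
  init_rec <- initial_records(dataset)
  trans_rec <- transition_records(dataset)
  cards <- as.integer(dataset$cardinalities)
  stacked <- c(cards, cards)
  n <- length(cards)
  cache <- score_cache()
  list(
    n = n,
    score_b0 = function(A) {
      static_k2_score(A, init_rec, cards, max_parents = max_parents,
                      cache = cache, tag = "initial")
    },
    score_trans = function(A) {
      .transition_score(A, trans_rec, stacked, n, max_parents, cache)
    }
  )
}

.score_candidate <- function(cand, scorer) {
  cand$k2_init <- scorer$score_b0(cand$b0)
  cand$k2_trans <- scorer$score_trans(cand$btrans)
  cand$score <- cand$k2_init + cand$k2_trans
  cand
}

# --- initialization ---------------------------------------------------------

# One random valid candidate: topological orders drawn from the RNG, edge
# inclusion gated by the chaotic stream.  The chaotic value is convolved
# with a uniform draw modulo 1, which keeps the stream in the loop while
# making the inclusion probability exactly p_edge (the raw logistic-sine
# sequence at r = 0.86 is far from uniform).
.random_candidate <- function(n, r, p_edge, max_parents) {
  stream <- .chaos_stream(r)
  chaos <- function(k) (stream(k) + stats::runif(k)) %% 1
  ord <- sample.int(n)
  b0 <- matrix(0L, n, n)
  if (n > 1L) {
    for (jj in 2:n) {
      child <- ord[jj]
      for (ii in 1:(jj - 1L)) {
        if (sum(b0[, child]) >= max_parents) break
        if (chaos(1L) < p_edge) b0[ord[ii], child] <- 1L
      }
    }
  }
  bt <- matrix(0L, 2L * n, 2L * n)
  ord_t1 <- n + sample.int(n)
  for (jj in seq_len(n)) {
    child <- ord_t1[jj]
    pool <- c(seq_len(n), if (jj > 1L) ord_t1[seq_len(jj - 1L)])
    for (p in pool) {
      if (sum(bt[, child]) >= max_parents) break
      if (chaos(1L) < p_edge) bt[p, child] <- 1L
    }
  }
  list(b0 = b0, btrans = bt, score = NA_real_, k2_init = NA_real_,
       k2_trans = NA_real_, hs = NA_real_, ped = NA_real_)
}

#' Initialize a population of candidate networks
#'
#' Draws `control$pop_size` valid candidates: a random topological order per
#' graph with edge inclusion gated by the logistic-sine chaotic stream at
#' probability `control$p_edge`, scored and with health set to the initial-
#' network score term.
#'
#' @param n Number of observed variables.
#' @param scorer Internal scorer (built by `dbn_learn()`); pass a
#'   `seq_dataset` to have one built.
#' @param control A `dbn_control()`.
#' @return List of candidate structures.
#' @export
init_structures <- function(n, scorer, control = dbn_control()) {
  if (inherits(scorer, "seq_dataset")) {
    scorer <- .make_scorer(scorer, control$max_parents)
  }
  lapply(seq_len(control$pop_size), function(s) {
    cand <- .random_candidate(n, control$r, control$p_edge,
                              control$max_parents)
    cand <- .score_candidate(cand, scorer)
    cand$hs <- cand$k2_init
    cand$ped <- control$ped0
    cand
  })
}

# --- chemotaxis -------------------------------------------------------------

# Try to make `A` agree with `target_A` on one differing off-diagonal cell,
# using whichever edge operation realizes the difference.
.adopt_difference <- function(A, target_A, cell_i, cell_j, n_slice,
                              max_parents) {
  if (target_A[cell_i, cell_j] == 1L) {
    if (A[cell_j, cell_i] == 1L && target_A[cell_j, cell_i] == 0L) {
      apply_edge_op(A, "reverse", cell_j, cell_i, n_slice = n_slice,
                    max_parents = max_parents)
    } else {
      apply_edge_op(A, "add", cell_i, cell_j, n_slice = n_slice,
                    max_parents = max_parents)
    }
  } else {
    apply_edge_op(A, "remove", cell_i, cell_j, n_slice = n_slice,
                  max_parents = max_parents)
  }
}

#' One structure-chemotaxis move
#'
#' The discrete analogue of the flip-and-swim move: a target is drawn
#' uniformly from the strictly better-scoring candidates (plus the best);
#' the candidate adopts 1 or 2 randomly chosen edge differences from the
#' target through valid edge operations (invalid proposals are skipped); the
#' proposal is kept iff the dynamic K2 score strictly increases, and on
#' improvement the move repeats toward the same target up to `ns` times.
#' Each accepted step adds the new transition-score term to the candidate's
#' health.
#'
#' @param idx Index of the moving candidate.
#' @param population List of scored candidates.
#' @param scorer Internal scorer.
#' @param control A `dbn_control()`.
#' @return The updated candidate.
#' @export
structure_chemotaxis <- function(idx, population, scorer, control) {
  cand <- population[[idx]]
  scores <- vapply(population, `[[`, numeric(1), "score")
  better <- which(scores > scores[idx])
  targets <- unique(c(better, which.max(scores)))
  tgt <- population[[targets[sample.int(length(targets), 1L)]]]
  n <- nrow(cand$b0)
  cells_b0 <- .offdiag_cells(n)
  cells_bt <- .offdiag_cells(2L * n)
  for (swim in seq_len(control$ns + 1L)) {
    diff_b0 <- which(cand$b0[cells_b0] != tgt$b0[cells_b0])
    diff_bt <- which(cand$btrans[cells_bt] != tgt$btrans[cells_bt])
    n_diff <- length(diff_b0) + length(diff_bt)
    if (n_diff == 0L) break
    intensity <- min(sample(c(1L, 2L), 1L), n_diff)
    picks <- sample.int(n_diff, intensity)
    prop_b0 <- cand$b0
    prop_bt <- cand$btrans
    for (p in picks) {
      if (p <= length(diff_b0)) {
        cell <- cells_b0[diff_b0[p], ]
        res <- .adopt_difference(prop_b0, tgt$b0, cell[1L], cell[2L],
                                 NULL, control$max_parents)
        if (res$ok) prop_b0 <- res$graph
      } else {
        cell <- cells_bt[diff_bt[p - length(diff_b0)], ]
        res <- .adopt_difference(prop_bt, tgt$btrans, cell[1L], cell[2L],
                                 n, control$max_parents)
        if (res$ok) prop_bt <- res$graph
      }
    }
    k2_init <- scorer$score_b0(prop_b0)
    k2_trans <- scorer$score_trans(prop_bt)
    if (k2_init + k2_trans > cand$score) {
      cand$b0 <- prop_b0
      cand$btrans <- prop_bt
      cand$k2_init <- k2_init
      cand$k2_trans <- k2_trans
      cand$score <- k2_init + k2_trans
      cand$hs <- cand$hs + k2_trans
    } else {
      break
    }
  }
  cand
}

#' Health score of a candidate
#'
#' The accumulated health: the initial-network score term plus the
#' transition-score term of every accepted chemotaxis step since the last
#' reproduction.
#'
#' @param candidate A candidate structure.
#' @return The health score HS.
#' @export
structure_health <- function(candidate) candidate$hs

# --- reproduction -----------------------------------------------------------

#' Health-ranked reproduction on encodings
#'
#' Ranks candidates by health (higher = healthier; scores are
#' log-probabilities), keeps the elite half, and with probability `pc`
#' replaces each lower-half candidate by a two-point crossover of its own
#' encoding (base) with its rank-matched elite's encoding (donor).  Offspring
#' are repaired by a fixed row-major bit scan that drops any edge violating
#' validity, then rescored.  Health resets to the initial-score term.
#'
#' @param population List of scored candidates.
#' @param scorer Internal scorer.
#' @param control A `dbn_control()`.
#' @return The updated population.
#' @export
reproduce_structures <- function(population, scorer, control) {
  s <- length(population)
  if (s %% 2L != 0L) stop("population size must be even", call. = FALSE)
  half <- s %/% 2L
  hs <- vapply(population, `[[`, numeric(1), "hs")
  ord <- order(hs, decreasing = TRUE)
  elites <- ord[seq_len(half)]
  worsts <- ord[seq.int(half + 1L, s)]
  n <- nrow(population[[1L]]$b0)
  len_b0 <- n * (n - 1L)
  for (k in seq_len(half)) {
    w <- worsts[k]
    if (stats::runif(1) < control$pc) {
      base <- candidate_bits(population[[w]]$b0, population[[w]]$btrans)
      donor <- candidate_bits(population[[elites[k]]]$b0,
                              population[[elites[k]]]$btrans)
      off <- two_point_crossover(base, donor)
      b0 <- .repair_bits(off[seq_len(len_b0)], n,
                         max_parents = control$max_parents)
      bt <- .repair_bits(off[-seq_len(len_b0)], 2L * n, n_slice = n,
                         max_parents = control$max_parents)
      cand <- population[[w]]
      cand$b0 <- b0
      cand$btrans <- bt
      cand <- .score_candidate(cand, scorer)
      population[[w]] <- cand
    }
  }
  for (i in seq_len(s)) population[[i]]$hs <- population[[i]]$k2_init
  population
}

# --- dispersal --------------------------------------------------------------

#' Adaptive structure dispersal
#'
#' Updates each candidate's dispersal probability from the historical health
#' extremes (a candidate at the historical minimum gets probability 1) and
#' independently re-initializes dispersed candidates; the current best-scoring
#' candidate is immune (elitism).
#'
#' @param population List of scored candidates.
#' @param hs_min,hs_max Historical health extremes.
#' @param scorer Internal scorer.
#' @param control A `dbn_control()`.
#' @return The updated population.
#' @export
structure_dispersal <- function(population, hs_min, hs_max, scorer, control) {
  scores <- vapply(population, `[[`, numeric(1), "score")
  best_idx <- which.max(scores)
  n <- nrow(population[[1L]]$b0)
  for (i in seq_along(population)) {
    population[[i]]$ped <- dispersal_probability(
      hs_min, hs_max, population[[i]]$hs, population[[i]]$ped)
    if (i == best_idx) next
    if (stats::runif(1) < population[[i]]$ped) {
      cand <- .random_candidate(n, control$r, control$p_edge,
                                control$max_parents)
      cand$ped <- population[[i]]$ped
      cand <- .score_candidate(cand, scorer)
      cand$hs <- cand$k2_init
      population[[i]] <- cand
    }
  }
  population
}

# --- main loop --------------------------------------------------------------

#' Learn a 2T-BN structure from sequence data
#'
#' Runs the foraging structure search: chaotic population initialization,
#' score-guided chemotaxis over edge operations, health-ranked crossover
#' reproduction and adaptive dispersal, maximizing the dynamic K2 score.
#' The reported network is the best-scoring structure ever evaluated.
#'
#' @param dataset A `seq_dataset`.
#' @param control A `dbn_control()`.
#' @param seed Optional integer seed.
#' @return A list of class `dbn_fit`: `network` (a `two_slice_bn`), `score`,
#'   `k2_initial`, `k2_transition`, `history` (per-generation best score,
#'   non-decreasing), `control`.
#' @export
dbn_learn <- function(dataset, control = dbn_control(), seed = NULL) {
  if (!inherits(dataset, "seq_dataset")) {
    stop("dataset must be a seq_dataset", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(dataset$nodes)
  scorer <- .make_scorer(dataset, control$max_parents)
  population <- lapply(seq_len(control$pop_size), function(s) {
    cand <- .random_candidate(n, control$r, control$p_edge,
                              control$max_parents)
    cand <- .score_candidate(cand, scorer)
    cand$hs <- cand$k2_init
    cand$ped <- control$ped0
    cand
  })
  scores <- vapply(population, `[[`, numeric(1), "score")
  best <- population[[which.max(scores)]]
  hs_all <- vapply(population, `[[`, numeric(1), "hs")
  hs_min <- min(hs_all); hs_max <- max(hs_all)

  history <- numeric(control$generations)
  for (g in seq_len(control$generations)) {
    for (sweep_i in seq_len(control$nc)) {
      for (i in seq_along(population)) {
        population[[i]] <- structure_chemotaxis(i, population, scorer,
                                                control)
        if (population[[i]]$score > best$score) best <- population[[i]]
      }
    }
    hs_all <- vapply(population, `[[`, numeric(1), "hs")
    hs_min <- min(hs_min, hs_all); hs_max <- max(hs_max, hs_all)
    if (g %% control$nre == 0L) {
      population <- reproduce_structures(population, scorer, control)
      sc <- vapply(population, `[[`, numeric(1), "score")
      if (max(sc) > best$score) best <- population[[which.max(sc)]]
    }
    if (g %% control$ned == 0L) {
      population <- structure_dispersal(population, hs_min, hs_max, scorer,
                                        control)
      sc <- vapply(population, `[[`, numeric(1), "score")
      if (max(sc) > best$score) best <- population[[which.max(sc)]]
    }
    history[g] <- best$score
  }
  nodes <- dataset$nodes
  b0 <- dbn_graph(best$b0, nodes = nodes)
  bt <- dbn_graph(best$btrans,
                  nodes = c(paste0(nodes, "_t"), paste0(nodes, "_t1")),
                  require_dag = FALSE)
  net <- two_slice_bn(b0, bt,
                      cardinalities = as.integer(dataset$cardinalities))
  structure(list(network = net, score = best$score,
                 k2_initial = best$k2_init, k2_transition = best$k2_trans,
                 history = history, control = control),
            class = "dbn_fit")
}

#' @export
print.dbn_fit <- function(x, ...) {
  cat(sprintf("learned 2T-BN: dynamic K2 = %.4f (initial %.4f + transition %.4f)\n",
              x$score, x$k2_initial, x$k2_transition))
  print(x$network)
  invisible(x)
}

#' Exhaustive dynamic-K2 maximum for small networks
#'
#' Brute-force oracle: enumerates every DAG for the initial network and, for
#' the transition network, every intra-slice DAG on the second slice combined
#' with every subset of previous-slice parents per node (decomposability
#' makes the per-node choice independent).  Practical for n <= 3-4 binary
#' nodes.
#'
#' @param dataset A `seq_dataset`.
#' @param max_parents Parent cap (as used by the learner).
#' @return A list: `score` (the attainable maximum), `b0` (an argmax initial
#'   adjacency), `btrans` (an argmax transition adjacency).
#' @export
exhaustive_dynamic_k2 <- function(dataset, max_parents = 4L) {
  n <- length(dataset$nodes)
  cards <- as.integer(dataset$cardinalities)
  init_rec <- initial_records(dataset)
  trans_rec <- transition_records(dataset)
  stacked <- c(cards, cards)
  dags <- enumerate_dags(n)

  b0_scores <- vapply(dags, function(A) {
    if (any(colSums(A) > max_parents)) return(-Inf)
    sum(vapply(seq_len(n), function(node) {
      log_k2_family(family_stats(init_rec, node, which(A[, node] == 1L),
                                 cards))
    }, numeric(1)))
  }, numeric(1))
  best_b0 <- dags[[which.max(b0_scores)]]

  fam_trans <- function(node, parents) {
    log_k2_family(family_stats(trans_rec, n + node, parents, stacked))
  }
  prev_subsets <- lapply(0:(2^n - 1), function(code) {
    which(as.integer(intToBits(code)[seq_len(n)]) == 1L)
  })
  # for each intra-slice DAG the previous-slice parent choice is independent
  # per node, so maximize each family separately
  best_tr_score <- -Inf
  best_tr <- NULL
  for (A_intra in dags) {
    total <- 0
    choice <- vector("list", n)
    feasible <- TRUE
    for (node in seq_len(n)) {
      intra_parents <- n + which(A_intra[, node] == 1L)
      node_best <- -Inf
      node_pick <- NULL
      for (ss in prev_subsets) {
        parents <- c(ss, intra_parents)
        if (length(parents) > max_parents) next
        val <- fam_trans(node, parents)
        if (val > node_best) {
          node_best <- val
          node_pick <- parents
        }
      }
      if (is.null(node_pick)) { feasible <- FALSE; break }
      total <- total + node_best
      choice[[node]] <- node_pick
    }
    if (!feasible) next
    if (total > best_tr_score) {
      best_tr_score <- total
      At <- matrix(0L, 2L * n, 2L * n)
      for (node in seq_len(n)) At[choice[[node]], n + node] <- 1L
      best_tr <- At
    }
  }
  list(score = max(b0_scores) + best_tr_score,
       b0 = best_b0, btrans = best_tr)
}
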