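# Independent oracles used across the suite.

# Naive K2 family score: direct products of factorials in log space via
# explicit sums of logs (no lgamma), following the marginal-likelihood
# product formula term by term.
naive_log_k2_family <- function(records, node, parents, cards) {
  r <- cards[node]
  log_fact <- function(n) if (n <= 1) 0 else sum(log(seq_len(n)))
  if (length(parents) == 0L) {
    configs <- matrix(0L, 1L, 0L)
  } else {
    configs <- as.matrix(expand.grid(lapply(cards[parents], function(cc) {
      0:(cc - 1L)
    })))
  }
  total <- 0
  for (j in seq_len(nrow(configs))) {
    if (length(parents) == 0L) {
      sel <- rep(TRUE, nrow(records))
    } else {
      sel <- rep(TRUE, nrow(records))
      for (p in seq_along(parents)) {
        sel <- sel & records[, parents[p]] == configs[j, p]
      }
    }
    n_ij <- sum(sel)
    term <- log_fact(r - 1L) - log_fact(n_ij + r - 1L)
    for (k in 0:(r - 1L)) {
      term <- term + log_fact(sum(sel & records[, node] == k))
    }
    total <- total + term
  }
  total
}

naive_static_k2 <- function(A, records, cards) {
  sum(vapply(seq_len(ncol(A)), function(node) {
    naive_log_k2_family(records, node, which(A[, node] == 1L), cards)
  }, numeric(1)))
}

# Acyclicity oracle through igraph (independent of the package's Kahn
# elimination).
igraph_is_dag <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  igraph::is_dag(g)
}

# Sample slice-0-style records from a single-edge structure A -> B with an
# asymmetric root; the configuration for which the true structure is the
# exhaustive K2 argmax.
sample_single_edge_records <- function(n, p_root = 0.3, strength = 0.9) {
  a <- stats::rbinom(n, 1L, p_root)
  b <- ifelse(stats::runif(n) < strength, a, 1L - a)
  cc <- stats::rbinom(n, 1L, 0.5)
  rec <- cbind(a, b, cc)
  storage.mode(rec) <- "integer"
  rec
}
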