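# Data model for two-slice dynamic Bayesian networks (2T-BNs): directed
# graphs as binary adjacency matrices, the row-wise bitstring encoding used by
# the structure search, conditional probability tables, and the forward
# sampler that generates discrete sequence data.

#' Directed graph over named nodes
#'
#' A thin validated wrapper around an n x n binary adjacency matrix with
#' `a[i, j] = 1` meaning i is a parent of j.  The diagonal must be zero and no
#' pair may be connected in both directions.  Acyclicity is checked separately
#' with `dag_is_acyclic()` because the transition network of a 2T-BN is only
#' required to be acyclic on its second slice.
#'
#' @param adjacency Square 0/1 matrix.
#' @param nodes Optional node names (default `X1..Xn` or dimnames).
#' @param require_dag Validate acyclicity (default TRUE).
#' @return An object of class `dbn_graph`.
#' @export
dbn_graph <- function(adjacency, nodes = NULL, require_dag = TRUE) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  if (ncol(A) != n) stop("adjacency must be square", call. = FALSE)
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary", call. = FALSE)
  storage.mode(A) <- "integer"
  if (any(diag(A) != 0L)) stop("self-loops are not allowed", call. = FALSE)
  if (any(A == 1L & t(A) == 1L)) {
    stop("bidirectional edge pair detected", call. = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- if (!is.null(rownames(A))) rownames(A) else paste0("X", seq_len(n))
  }
  if (length(nodes) != n) stop("node name count mismatch", call. = FALSE)
  dimnames(A) <- list(nodes, nodes)
  g <- structure(list(n = n, adjacency = A, nodes = nodes),
                 class = "dbn_graph")
  if (require_dag && !dag_is_acyclic(g)) {
    stop("graph contains a cycle", call. = FALSE)
  }
  g
}

#' @export
print.dbn_graph <- function(x, ...) {
  e <- which(x$adjacency == 1L, arr.ind = TRUE)
  cat(sprintf("directed graph: %d nodes, %d edges\n", x$n, nrow(e)))
  if (nrow(e) > 0) {
    cat(paste(x$nodes[e[, 1]], "->", x$nodes[e[, 2]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Acyclicity test
#'
#' Kahn-style elimination on the adjacency matrix: repeatedly remove nodes
#' without unremoved parents; the graph is acyclic iff all nodes get removed.
#'
#' @param graph A `dbn_graph` or a binary adjacency matrix.
#' @return TRUE iff a topological order exists.
#' @export
dag_is_acyclic <- function(graph) {
  A <- if (inherits(graph, "dbn_graph")) graph$adjacency else graph
  n <- nrow(A)
  if (n == 0L) return(TRUE)
  alive <- rep(TRUE, n)
  indeg <- colSums(A)
  repeat {
    free <- alive & indeg == 0L
    if (!any(free)) break
    alive[free] <- FALSE
    out <- which(free)
    for (i in out) indeg <- indeg - A[i, ]
  }
  !any(alive)
}

# Topological order of a DAG adjacency matrix (assumes acyclic).
.topo_order <- function(A) {
  n <- nrow(A)
  order <- integer(0)
  alive <- rep(TRUE, n)
  indeg <- colSums(A)
  while (length(order) < n) {
    free <- which(alive & indeg == 0L)
    if (length(free) == 0L) stop("cycle encountered in topological sort")
    order <- c(order, free)
    alive[free] <- FALSE
    for (i in free) indeg <- indeg - A[i, ]
  }
  order
}

#' Encode a graph as a row-wise bitstring
#'
#' For each row i the n-1 off-diagonal entries (ascending column index,
#' skipping the diagonal) are written as a bit run; rows are joined with
#' `"|"`.  A 3-node graph with edges 1->2, 1->3, 2->3 encodes as
#' `"11|01|00"`.
#'
#' @param graph A `dbn_graph`.
#' @return A single string.
#' @export
encode_graph <- function(graph) {
  A <- graph$adjacency
  n <- graph$n
  rows <- vapply(seq_len(n), function(i) {
    paste(A[i, -i], collapse = "")
  }, character(1))
  paste(rows, collapse = "|")
}

#' Decode a row-wise bitstring into a graph
#'
#' Inverse of `encode_graph()`: expects n rows of n-1 bits separated by
#' `"|"`.  The result is validated (no self-loops, no bidirectional pairs;
#' acyclicity when `require_dag`).
#'
#' @param text Encoded string.
#' @param n Node count.
#' @param nodes Optional node names.
#' @param require_dag Validate acyclicity.
#' @return A `dbn_graph`.
#' @export
decode_graph <- function(text, n, nodes = NULL, require_dag = TRUE) {
  rows <- strsplit(text, "|", fixed = TRUE)[[1]]
  if (length(rows) != n) {
    stop(sprintf("expected %d rows in encoding, got %d", n, length(rows)),
         call. = FALSE)
  }
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    bits <- strsplit(rows[i], "")[[1]]
    if (length(bits) != n - 1L || !all(bits %in% c("0", "1"))) {
      stop(sprintf("row %d must contain %d bits", i, n - 1L), call. = FALSE)
    }
    A[i, setdiff(seq_len(n), i)] <- as.integer(bits)
  }
  dbn_graph(A, nodes = nodes, require_dag = require_dag)
}

#' Temporal validity of a transition network
#'
#' A transition graph over 2n slice-labelled nodes (first n = slice t, last
#' n = slice t+1) is temporally valid iff no edge targets a slice-t node and
#' the subgraph induced on the slice-t+1 nodes is acyclic.  Intra-slice edges
#' among the t+1 nodes are permitted.
#'
#' @param btrans A `dbn_graph` over 2n nodes (or adjacency matrix).
#' @param n Per-slice node count.
#' @return TRUE iff temporally valid.
#' @export
check_temporal <- function(btrans, n) {
  A <- if (inherits(btrans, "dbn_graph")) btrans$adjacency else btrans
  if (nrow(A) != 2L * n) stop("transition graph must have 2n nodes",
                              call. = FALSE)
  slice_t <- seq_len(n)
  if (any(A[, slice_t] == 1L)) return(FALSE)
  dag_is_acyclic(A[-slice_t, -slice_t, drop = FALSE])
}

#' Two-slice dynamic Bayesian network
#'
#' Bundles the initial network `b0` (a DAG over n nodes describing the first
#' time slice) with the transition network `btrans` (a temporally valid graph
#' over 2n slice-labelled nodes; the first n represent slice t, the last n
#' slice t+1).  The structure is assumed time-invariant: one transition
#' network applies at every step.
#'
#' @param b0 `dbn_graph` over n nodes.
#' @param btrans `dbn_graph` over 2n nodes.
#' @param cardinalities Integer vector of per-node state counts (default
#'   binary).
#' @param cpts Optional CPT set from `make_fixture_cpts()` or compatible.
#' @return An object of class `two_slice_bn`.
#' @export
two_slice_bn <- function(b0, btrans, cardinalities = NULL, cpts = NULL) {
  n <- b0$n
  if (btrans$n != 2L * n) {
    stop("transition network must have twice the nodes of the initial network",
         call. = FALSE)
  }
  if (!dag_is_acyclic(b0)) stop("initial network must be acyclic",
                                call. = FALSE)
  if (!check_temporal(btrans, n)) {
    stop("transition network violates temporal validity", call. = FALSE)
  }
  if (is.null(cardinalities)) cardinalities <- rep(2L, n)
  stopifnot(length(cardinalities) == n, all(cardinalities >= 2L))
  structure(list(n = n, b0 = b0, btrans = btrans,
                 cardinalities = as.integer(cardinalities), cpts = cpts),
            class = "two_slice_bn")
}

#' @export
print.two_slice_bn <- function(x, ...) {
  cat(sprintf("two-slice DBN over %d nodes (%s)\n", x$n,
              paste(x$b0$nodes, collapse = ", ")))
  cat(" initial   :", encode_graph(x$b0), "\n")
  cat(" transition:", encode_graph(x$btrans), "\n")
  invisible(x)
}

#' Random DAG
#'
#' Draws a uniform topological order, then proposes each backward edge
#' independently with probability `p_edge`, honouring a per-node parent cap.
#' Acyclicity holds by construction.
#'
#' @param n Node count.
#' @param max_parents Parent cap per node.
#' @param p_edge Edge inclusion probability.
#' @param nodes Optional node names.
#' @return A `dbn_graph`.
#' @export
random_dag <- function(n, max_parents = 4L, p_edge = 0.5, nodes = NULL) {
  ord <- sample.int(n)
  A <- matrix(0L, n, n)
  if (max_parents > 0L && n > 1L) {
    for (j in 2:n) {
      child <- ord[j]
      for (i in 1:(j - 1L)) {
        parent <- ord[i]
        if (sum(A[, child]) >= max_parents) break
        if (stats::runif(1) < p_edge) A[parent, child] <- 1L
      }
    }
  }
  dbn_graph(A, nodes = nodes)
}

#' Enumerate all labelled DAGs on n nodes
#'
#' Exhaustive generation by filtering every orientation pattern; practical
#' for n <= 4 (n = 3 yields the known 25 labelled DAGs).  Used as the
#' brute-force oracle for small-instance structure search.
#'
#' @param n Node count (small).
#' @return List of adjacency matrices.
#' @export
enumerate_dags <- function(n) {
  slots <- which(upper.tri(matrix(0, n, n)) | lower.tri(matrix(0, n, n)))
  m <- length(slots)
  out <- list()
  for (code in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(code)[seq_len(m)])
    A <- matrix(0L, n, n)
    A[slots] <- bits
    if (any(A == 1L & t(A) == 1L)) next
    if (!dag_is_acyclic(A)) next
    out[[length(out) + 1L]] <- A
  }
  out
}

# --- CPTs -------------------------------------------------------------------

# A CPT set is a list with $b0 and $btrans, each a list over child nodes:
# list(parents = integer parent indices (into the slice-0 nodes for b0, into
# the 2n stacked nodes for btrans), table = q x r matrix of P(child = k |
# parent configuration j)), rows summing to 1.  Parent configurations are
# indexed with the FIRST parent as the fastest-varying digit.

.validate_cpt_table <- function(tab) {
  stopifnot(all(tab >= 0), all(tab <= 1))
  if (any(abs(rowSums(tab) - 1) > 1e-12)) {
    stop("CPT rows must sum to 1", call. = FALSE)
  }
  invisible(tab)
}

# Map parent state values (matrix, columns = parents, 0-based) to 1-based
# configuration indices.
.parent_config <- function(vals, cards) {
  if (length(cards) == 0L) return(rep(1L, nrow(vals)))
  idx <- rep(0L, nrow(vals))
  stride <- 1L
  for (p in seq_along(cards)) {
    idx <- idx + vals[, p] * stride
    stride <- stride * cards[p]
  }
  idx + 1L
}

#' Fixture CPTs with strong parent-child coupling
#'
#' Deterministically (given `seed`) builds a CPT set for a binary 2T-BN in
#' which every child copies its first listed parent with probability
#' `strength`, and every root's success probability is drawn uniformly from
#' `[0.3, 0.7]`.  These are fixture choices for generating synthetic data
#' with recoverable structure; they are not estimates of anything.
#'
#' @param bn A `two_slice_bn` (binary nodes).
#' @param strength Copy probability of the designated parent.
#' @param seed Integer seed controlling the root probabilities.
#' @return A CPT set suitable for `forward_sample()`.
#' @export
make_fixture_cpts <- function(bn, strength = 0.9, seed = 1L) {
  stopifnot(all(bn$cardinalities == 2L))
  n <- bn$n
  rng_state <- .save_rng()
  on.exit(.restore_rng(rng_state))
  set.seed(as.integer(seed))
  root_p <- stats::runif(2L * n, 0.3, 0.7)
  build <- function(A, child, offset) {
    parents <- as.integer(unname(which(A[, child] == 1L)))
    q <- 2L^length(parents)
    tab <- matrix(0, q, 2L)
    if (length(parents) == 0L) {
      p1 <- root_p[child + offset]
      tab[1, ] <- c(1 - p1, p1)
    } else {
      # configuration index: first parent fastest-varying
      for (j in seq_len(q)) {
        cfg <- (j - 1L)
        first_parent_state <- cfg %% 2L
        p_copy <- if (first_parent_state == 1L) strength else 1 - strength
        tab[j, ] <- c(1 - p_copy, p_copy)
      }
    }
    .validate_cpt_table(tab)
    list(parents = parents, table = tab)
  }
  b0_cpts <- lapply(seq_len(n), function(ch) build(bn$b0$adjacency, ch, 0L))
  btrans_cpts <- lapply(seq_len(n), function(ch) {
    build(bn$btrans$adjacency, n + ch, 0L)
  })
  list(b0 = b0_cpts, btrans = btrans_cpts)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Toy three-node 2T-BN fixture
#'
#' The canonical small example used throughout the tests: a fully connected
#' three-node initial DAG (`"11|01|00"`) and a six-node transition graph
#' (`"00110|00011|00001|00010|00001|00000"`) over binary variables, with
#' strong fixture CPTs from `make_fixture_cpts()`.
#'
#' @param seed Seed for the fixture CPT root probabilities.
#' @param strength Parent-copy probability of the fixture CPTs.
#' @return A `two_slice_bn` with CPTs attached.
#' @export
toy_network <- function(seed = 1L, strength = 0.9) {
  nodes <- c("A", "B", "C")
  b0 <- decode_graph("11|01|00", 3L, nodes = nodes)
  bt <- decode_graph("00110|00011|00001|00010|00001|00000", 6L,
                     nodes = c(paste0(nodes, "_t"), paste0(nodes, "_t1")),
                     require_dag = FALSE)
  bn <- two_slice_bn(b0, bt)
  bn$cpts <- make_fixture_cpts(bn, strength = strength, seed = seed)
  bn
}

# --- sampling ---------------------------------------------------------------

.sample_discrete <- function(prob_rows) {
  # prob_rows: m x r matrix; returns m draws (0-based states)
  m <- nrow(prob_rows)
  u <- stats::runif(m)
  cum <- t(apply(prob_rows, 1L, cumsum))
  if (m == 1L) cum <- matrix(cum, nrow = 1L)
  rowSums(u > cum)
}

#' Forward-sample sequences from a 2T-BN
#'
#' Ancestral sampling: slice 0 from the initial network's CPTs in topological
#' order, every later slice from the transition CPTs conditioned on the
#' previous slice (second-slice nodes sampled in the topological order of
#' their intra-slice subgraph).
#'
#' @param bn A `two_slice_bn` with CPTs attached.
#' @param n_seq Number of sequences N.
#' @param n_slices Slices per sequence (>= 1).
#' @param seed Optional seed.
#' @return A `seq_dataset`: list with `data` (data.frame with columns
#'   `sequence_id`, `time`, one integer-coded column per node),
#'   `nodes`, `cardinalities`.
#' @export
forward_sample <- function(bn, n_seq, n_slices, seed = NULL) {
  if (is.null(bn$cpts)) stop("network has no CPTs", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- bn$n
  ord0 <- .topo_order(bn$b0$adjacency)
  intra <- bn$btrans$adjacency[(n + 1):(2 * n), (n + 1):(2 * n), drop = FALSE]
  ord_t <- .topo_order(intra)
  cards <- bn$cardinalities

  # states[s, node] per slice; all sequences advanced in lock-step
  slices <- vector("list", n_slices)
  cur <- matrix(0L, n_seq, n)
  for (node in ord0) {
    cpt <- bn$cpts$b0[[node]]
    if (length(cpt$parents) == 0L) {
      cfg <- rep(1L, n_seq)
    } else {
      cfg <- .parent_config(cur[, cpt$parents, drop = FALSE],
                            cards[cpt$parents])
    }
    cur[, node] <- .sample_discrete(cpt$table[cfg, , drop = FALSE])
  }
  slices[[1]] <- cur
  if (n_slices > 1L) {
    for (t in 2:n_slices) {
      prev <- slices[[t - 1L]]
      nxt <- matrix(0L, n_seq, n)
      stacked_cards <- c(cards, cards)
      for (node in ord_t) {
        cpt <- bn$cpts$btrans[[node]]
        if (length(cpt$parents) == 0L) {
          cfg <- rep(1L, n_seq)
        } else {
          vals <- sapply(cpt$parents, function(p) {
            if (p <= n) prev[, p] else nxt[, p - n]
          })
          if (n_seq == 1L) vals <- matrix(vals, nrow = 1L)
          cfg <- .parent_config(vals, stacked_cards[cpt$parents])
        }
        nxt[, node] <- .sample_discrete(cpt$table[cfg, , drop = FALSE])
      }
      slices[[t]] <- nxt
    }
  }
  df <- do.call(rbind, lapply(seq_len(n_slices), function(t) {
    data.frame(sequence_id = seq_len(n_seq), time = t - 1L, slices[[t]])
  }))
  names(df) <- c("sequence_id", "time", bn$b0$nodes)
  df <- df[order(df$sequence_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  seq_dataset(df, cardinalities = cards)
}

#' Discrete sequence dataset
#'
#' Validates and wraps a long-format table of integer-coded states with
#' columns `sequence_id`, `time` and one column per node.  Time indices must
#' be contiguous from 0 within each sequence.
#'
#' @param data A data.frame in long format.
#' @param cardinalities Optional per-node state counts; inferred as
#'   `max + 1` (at least 2) when missing.
#' @return An object of class `seq_dataset`.
#' @export
seq_dataset <- function(data, cardinalities = NULL) {
  need <- c("sequence_id", "time")
  if (!all(need %in% names(data))) {
    stop("dataset needs sequence_id and time columns", call. = FALSE)
  }
  nodes <- setdiff(names(data), need)
  if (length(nodes) == 0L) stop("dataset has no node columns", call. = FALSE)
  data <- data[order(data$sequence_id, data$time), , drop = FALSE]
  rownames(data) <- NULL
  vals <- as.matrix(data[, nodes, drop = FALSE])
  if (any(vals != floor(vals)) || any(vals < 0)) {
    stop("states must be non-negative integers", call. = FALSE)
  }
  storage.mode(vals) <- "integer"
  for (k in seq_along(nodes)) data[[nodes[k]]] <- vals[, k]
  data$sequence_id <- as.integer(data$sequence_id)
  data$time <- as.integer(data$time)
  if (is.null(cardinalities)) {
    cardinalities <- pmax(apply(vals, 2L, max) + 1L, 2L)
  }
  cardinalities <- as.integer(cardinalities)
  if (any(vals >= matrix(cardinalities, nrow(vals), length(nodes),
                         byrow = TRUE))) {
    stop("state value exceeds declared cardinality", call. = FALSE)
  }
  lens <- tapply(data$time, data$sequence_id, function(tt) {
    if (!identical(as.integer(sort(tt)), seq.int(0L, length(tt) - 1L))) {
      stop("time indices must be contiguous from 0 within each sequence",
           call. = FALSE)
    }
    length(tt)
  })
  structure(list(data = data, nodes = nodes,
                 cardinalities = stats::setNames(cardinalities, nodes),
                 n_seq = length(lens),
                 lengths = as.integer(lens)),
            class = "seq_dataset")
}

#' @export
print.seq_dataset <- function(x, ...) {
  cat(sprintf("sequence dataset: %d sequences, %d total slices, %d nodes (%s)\n",
              x$n_seq, sum(x$lengths), length(x$nodes),
              paste(x$nodes, collapse = ", ")))
  invisible(x)
}

#' First-slice records of a dataset
#'
#' @param dataset A `seq_dataset`.
#' @return Integer matrix (one row per sequence, columns = nodes) of the
#'   slice-0 states, used to score the initial network.
#' @export
initial_records <- function(dataset) {
  d <- dataset$data
  m <- as.matrix(d[d$time == 0L, dataset$nodes, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Stacked transition records
#'
#' Flattens every adjacent slice pair of every sequence into one record with
#' 2n columns: the slice-t values followed by the slice-t+1 values.  A
#' sequence of length L contributes L-1 records; length-1 sequences
#' contribute none.
#'
#' @param dataset A `seq_dataset`.
#' @return Integer matrix with `sum(pmax(lengths - 1, 0))` rows and 2n
#'   columns named `<node>_t`, `<node>_t1`.
#' @export
transition_records <- function(dataset) {
  d <- dataset$data
  nodes <- dataset$nodes
  vals <- as.matrix(d[, nodes, drop = FALSE])
  storage.mode(vals) <- "integer"
  # rows are sorted by (sequence, time): pair each row with its successor
  # within the same sequence
  same_seq <- d$sequence_id[-1L] == d$sequence_id[-nrow(d)]
  from <- which(same_seq)
  out <- cbind(vals[from, , drop = FALSE], vals[from + 1L, , drop = FALSE])
  colnames(out) <- c(paste0(nodes, "_t"), paste0(nodes, "_t1"))
  out
}
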