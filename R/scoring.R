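# K2 Bayesian-Dirichlet scoring.  The static score of a DAG given complete
# discrete data decomposes over node families; the dynamic score of a 2T-BN
# adds an initial-network term (first-slice records) and a transition term
# (second-slice families on stacked adjacent-slice records).  Log factorials
# go through lgamma, exact to double precision for integer counts.

#' Sufficient statistics for one node family
#'
#' Counts `N_ij` (records per parent configuration j) and `N_ijk` (records
#' with the child in state k under configuration j) for a node and parent
#' set.  Configurations index the first parent fastest.
#'
#' @param records Integer matrix of records (columns = variables, 0-based
#'   states).
#' @param node Child column index.
#' @param parents Integer vector of parent column indices (possibly empty).
#' @param cardinalities State counts per column of `records`.
#' @return A list of class `family_stats`: `node`, `parents`, `r` (child
#'   cardinality), `q` (configuration count), `n_ij` (length q), `n_ijk`
#'   (q x r matrix).
#' @export
family_stats <- function(records, node, parents, cardinalities) {
  r <- as.integer(cardinalities[node])
  q <- if (length(parents) == 0L) 1L else
    as.integer(prod(cardinalities[parents]))
  if (nrow(records) == 0L) {
    n_ijk <- matrix(0L, q, r)
  } else {
    child <- records[, node]
    if (any(child < 0L | child >= r)) {
      stop("child state out of range", call. = FALSE)
    }
    if (length(parents) == 0L) {
      cfg <- rep(1L, nrow(records))
    } else {
      pv <- records[, parents, drop = FALSE]
      pc <- cardinalities[parents]
      if (any(pv < 0L) ||
          any(pv >= matrix(pc, nrow(pv), length(parents), byrow = TRUE))) {
        stop("parent state out of range", call. = FALSE)
      }
      cfg <- .parent_config(pv, pc)
    }
    joint <- cfg + q * child   # 1..q*r
    n_ijk <- matrix(tabulate(joint, nbins = q * r), q, r)
  }
  structure(list(node = node, parents = parents, r = r, q = q,
                 n_ij = rowSums(n_ijk), n_ijk = n_ijk),
            class = "family_stats")
}

#' Log K2 family score
#'
#' \deqn{\sum_j \left[\log(r-1)! - \log(N_{ij}+r-1)! +
#'       \sum_k \log N_{ijk}!\right]}
#' computed with `lgamma`; zero when all counts are zero.
#'
#' @param stats A `family_stats` object.
#' @return The log marginal-likelihood contribution of the family.
#' @export
log_k2_family <- function(stats) {
  r <- stats$r
  sum(lgamma(r) - lgamma(stats$n_ij + r)) + sum(lgamma(stats$n_ijk + 1))
}

#' Family score cache
#'
#' A hash environment keyed by (segment tag, node, ordered parent tuple);
#' hits return bit-identical values to fresh computation.  One cache is
#' scoped to one dataset.
#'
#' @return An object of class `score_cache`.
#' @export
score_cache <- function() {
  structure(list(env = new.env(parent = emptyenv())), class = "score_cache")
}

.cached_family_score <- function(cache, tag, records, node, parents,
                                 cardinalities) {
  key <- paste0(tag, ":", node, ":", paste(parents, collapse = ","))
  if (!is.null(cache)) {
    hit <- cache$env[[key]]
    if (!is.null(hit)) return(hit)
  }
  val <- log_k2_family(family_stats(records, node, parents, cardinalities))
  if (!is.null(cache)) cache$env[[key]] <- val
  val
}

#' Static K2 score of a DAG
#'
#' Sum of `log_k2_family()` over every node with its parent set read from
#' the graph.  Decomposable: an edge change touches exactly one family term.
#'
#' @param graph A `dbn_graph` (acyclic) or adjacency matrix.
#' @param records Integer record matrix (columns aligned with graph nodes,
#'   0-based states).
#' @param cardinalities Per-node state counts.
#' @param max_parents Guard on family size (configuration blow-up).
#' @param cache Optional `score_cache()` scoped to these records.
#' @param tag Cache segment tag.
#' @return The log K2 score.
#' @export
static_k2_score <- function(graph, records, cardinalities,
                            max_parents = 4L, cache = NULL, tag = "static") {
  A <- if (inherits(graph, "dbn_graph")) graph$adjacency else graph
  n <- ncol(A)
  total <- 0
  for (node in seq_len(n)) {
    parents <- which(A[, node] == 1L)
    if (length(parents) > max_parents) {
      stop(sprintf("node %d has %d parents, exceeding max_parents = %d",
                   node, length(parents), max_parents), call. = FALSE)
    }
    total <- total + .cached_family_score(cache, tag, records, node, parents,
                                          cardinalities)
  }
  total
}

#' Dynamic K2 score of a 2T-BN
#'
#' \eqn{Score = K2_0 + K2_\to}: the static K2 score of the initial network
#' on the first-slice records plus the sum of family scores of the
#' slice-t+1 nodes of the transition network on the stacked transition
#' records (parents may come from either slice).
#'
#' @param bn A `two_slice_bn`, or a list with `b0`/`btrans` graphs.
#' @param dataset A `seq_dataset`.
#' @param max_parents Family-size guard.
#' @param cache Optional `score_cache()` scoped to this dataset.
#' @param components Return the two terms alongside the total.
#' @return The total score, or (with `components = TRUE`) a list with
#'   `k2_initial`, `k2_transition`, `total`.
#' @export
dynamic_k2_score <- function(bn, dataset, max_parents = 4L, cache = NULL,
                             components = FALSE) {
  n <- bn$n
  cards <- as.integer(dataset$cardinalities)
  init <- static_k2_score(bn$b0, initial_records(dataset), cards,
                          max_parents = max_parents, cache = cache,
                          tag = "initial")
  trans_rec <- transition_records(dataset)
  k2t <- .transition_score(bn$btrans, trans_rec, c(cards, cards),
                           n, max_parents, cache)
  if (components) {
    list(k2_initial = init, k2_transition = k2t, total = init + k2t)
  } else {
    init + k2t
  }
}

# Transition term: families of the slice-t+1 nodes only.
.transition_score <- function(btrans, trans_records, stacked_cards, n,
                              max_parents, cache) {
  A <- if (inherits(btrans, "dbn_graph")) btrans$adjacency else btrans
  total <- 0
  for (node in (n + 1L):(2L * n)) {
    parents <- which(A[, node] == 1L)
    if (length(parents) > max_parents) {
      stop(sprintf("transition node %d exceeds max_parents = %d",
                   node, max_parents), call. = FALSE)
    }
    total <- total + .cached_family_score(cache, "transition", trans_records,
                                          node, parents, stacked_cards)
  }
  total
}
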